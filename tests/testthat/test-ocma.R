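# shared synthetic two-vessel scene used across angiography tests
ocma_scene <- function(seed = 9, dynamic_contrast = 0.5, noise_sd = 0.05) {
  angio_spec(volume_shape = c(40, 40), voxel_size = 2,
             vessel_segments = list(
               list(a = c(5, 5), b = c(35, 35), radius_um = 3, perfused = TRUE),
               list(a = c(5, 35), b = c(35, 5), radius_um = 3, perfused = TRUE)),
             frames_per_timepoint = 16, dynamic_contrast = dynamic_contrast,
             noise_sd = noise_sd, seed = seed)
}

test_that("angiograms separate perfused vessels from static background", {
  # perfectly static stack -> identically zero map
  static <- array(rep(matrix(runif(100), 10, 10), 8), c(10, 10, 8))
  static <- aperm(static, c(3, 1, 2))
  expect_true(all(compute_angiogram(static)$map == 0))
  expect_error(compute_angiogram(static[1:3, , ]), "4 frames")

  s <- generate_angio_timeseries(ocma_scene(), "t0")
  msk <- attr(s, "mask")
  a <- compute_angiogram(s$t0)
  expect_true(all(a$map >= 0))
  expect_gt(mean(a$map[msk]), 5 * mean(a$map[!msk]))

  # rms filter variant gives the same separation
  a2 <- compute_angiogram(s$t0, method = "rms")
  expect_gt(mean(a2$map[msk]), 5 * mean(a2$map[!msk]))
})

test_that("angiogram is linear in dynamic contrast and offset-invariant", {
  spec1 <- ocma_scene(seed = 40, dynamic_contrast = 0.3, noise_sd = 0)
  spec2 <- ocma_scene(seed = 40, dynamic_contrast = 0.6, noise_sd = 0)
  m1 <- compute_angiogram(generate_angio_timeseries(spec1, "t")$t)$map
  m2 <- compute_angiogram(generate_angio_timeseries(spec2, "t")$t)$map
  msk <- attr(generate_angio_timeseries(spec1, "t"), "mask")
  expect_equal(m2[msk], 2 * m1[msk], tolerance = 1e-10)

  # adding a static offset image to every frame changes nothing
  s <- generate_angio_timeseries(ocma_scene(seed = 41), "t")$t
  offset <- matrix(runif(prod(dim(s)[2:3]), 0, 5), dim(s)[2], dim(s)[3])
  s_off <- sweep(s, 2:3, offset, "+")
  expect_equal(compute_angiogram(s_off)$map, compute_angiogram(s)$map,
               tolerance = 1e-10)
})

test_that("stallogram flags follow the generator's perfusion schedule", {
  spec <- ocma_scene(seed = 14)
  sched <- rbind(TRUE, FALSE, FALSE, TRUE) # vessel 1 on/off/off/on
  series <- generate_angio_timeseries(spec, paste0("t", 1:4),
                                      schedule = cbind(sched, TRUE))
  angios <- lapply(series, compute_angiogram)
  msks <- attr(series, "segment_masks")
  vroi <- msks[[1]] & !msks[[2]]
  broi <- !attr(series, "mask")
  tr <- stallogram(angios, vroi, broi, times = c(0, 60, 120, 180))
  expect_equal(tr$stalled, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(tr$t_s, c(0, 60, 120, 180))
  # stalled timepoints sit at baseline ~1
  expect_lt(max(abs(tr$norm_intensity[tr$stalled] - 1)), 0.25)

  # global multiplicative gain leaves the normalized trace unchanged
  gained <- lapply(angios, function(a) a$map * 7.3)
  tg <- stallogram(gained, vroi, broi)
  expect_equal(tg$norm_intensity, tr$norm_intensity, tolerance = 1e-12)

  # vessel ROI statistically identical to background -> ~1 and stalled
  b2 <- broi & row(broi) <= 20
  b1 <- broi & row(broi) > 20
  t_id <- stallogram(angios[1], b1, b2)
  expect_lt(abs(t_id$norm_intensity - 1), 0.1)
  expect_true(t_id$stalled)

  expect_error(stallogram(angios, vroi, vroi), "disjoint")
  expect_error(stallogram(angios, vroi & FALSE, broi), "non-empty")
})

test_that("longitudinal tracking detects the insult and its recovery", {
  spec <- ocma_scene(seed = 15)
  labels <- c("pre", "0h", "2h", "4h", "24h")
  sched <- cbind(c(TRUE, FALSE, FALSE, FALSE, TRUE), TRUE)
  series <- generate_angio_timeseries(spec, labels, schedule = sched)
  angios <- lapply(series, compute_angiogram)
  msks <- attr(series, "segment_masks")
  vroi <- msks[[1]] & !msks[[2]]
  broi <- !attr(series, "mask")
  tk <- track_insult(angios, vroi, broi)
  expect_equal(tk$status$perfused, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(tk$insult_detected)
  expect_equal(tk$onset, "0h")
  expect_equal(tk$recovered_at, "24h")

  # all perfused: no insult
  series_ok <- generate_angio_timeseries(spec, labels)
  tk_ok <- track_insult(lapply(series_ok, compute_angiogram), vroi, broi)
  expect_false(tk_ok$insult_detected)
  expect_true(is.na(tk_ok$recovered_at))

  expect_error(track_insult(list(angios[[1]]), vroi, broi))
})

test_that("stalled flags equal the schedule whenever contrast >= 5x noise", {
  labels <- paste0("t", 1:3)
  sched <- cbind(c(TRUE, FALSE, TRUE), TRUE)
  for (pars in list(c(0.25, 0.05), c(0.5, 0.1), c(1, 0.05))) {
    spec <- ocma_scene(seed = 50, dynamic_contrast = pars[1], noise_sd = pars[2])
    series <- generate_angio_timeseries(spec, labels, schedule = sched)
    angios <- lapply(series, compute_angiogram)
    msks <- attr(series, "segment_masks")
    vroi <- msks[[1]] & !msks[[2]]
    broi <- !attr(series, "mask")
    tr <- stallogram(angios, vroi, broi)
    expect_equal(tr$stalled, !sched[, 1])
  }
})

test_that("translation registration recovers known shifts", {
  set.seed(77)
  ref <- matrix(rnorm(64 * 64), 64, 64)
  for (shift in list(c(0, 0), c(3, -5), c(-7, 2))) {
    mov <- shift_array(ref, shift)
    est <- register_translation(ref, mov)
    expect_equal(shift_array(mov, est)[10:50, 10:50], ref[10:50, 10:50])
  }
})
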
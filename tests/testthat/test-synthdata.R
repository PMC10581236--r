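test_that("kymograph generator honors rate, stalls and determinism", {
  # empty case: no RBCs, noiseless -> flat plasma band
  sp0 <- kymo_spec(n_lines = 800, rbc_rate = 0, noise_sd = 0, seed = 1)
  k0 <- generate_kymograph(sp0)
  expect_equal(nrow(attr(k0, "truth")), 0)
  expect_true(all(k0$image == 1))

  # Poisson passage count: 30 s at 10 cells/s, 99% band of Poisson(300)
  sp <- kymo_spec(n_lines = 24000, rbc_rate = 10, seed = 11)
  n <- nrow(attr(generate_kymograph(sp), "truth"))
  band <- qpois(c(0.005, 0.995), 300)
  expect_gte(n, band[1])
  expect_lte(n, band[2])

  # no passages inside a stall interval
  sps <- kymo_spec(n_lines = 24000, rbc_rate = 10, seed = 2,
                   stall_intervals = list(c(5, 25)))
  tr <- attr(generate_kymograph(sps), "truth")
  expect_false(any(tr$entry_s > 5 & tr$entry_s < 25))

  # same seed bit-identical, different seed different
  k1 <- generate_kymograph(kymo_spec(n_lines = 2000, rbc_rate = 8, seed = 5))
  k2 <- generate_kymograph(kymo_spec(n_lines = 2000, rbc_rate = 8, seed = 5))
  k3 <- generate_kymograph(kymo_spec(n_lines = 2000, rbc_rate = 8, seed = 6))
  expect_identical(k1$image, k2$image)
  expect_false(identical(attr(k1, "truth"), attr(k3, "truth")))
})

test_that("generated streak slope equals 1/speed by brute-force pixel tracing", {
  # single passage, noiseless; slope measured by per-row shadow centroids
  for (speed in c(0.5, 1, 2)) {
    sp <- kymo_spec(n_lines = 1600, rbc_rate = 0.5, rbc_speed = speed,
                    rbc_speed_cv = 0, noise_sd = 0, seed = 8)
    k <- generate_kymograph(sp)
    tr <- attr(k, "truth")
    expect_equal(nrow(tr), 1) # scenario built to hold exactly one streak
    measured <- trace_streak_slope(k)
    truth_slope <- 1 / (speed * 1000) # s/µm
    # within one pixel/line of quantization
    tol <- max(1 / k$line_rate / k$pixel_pitch * 0.5, 0.05 * truth_slope)
    expect_lt(abs(measured - truth_slope), tol)
  }
})

test_that("kymo_spec rejects invalid parameters", {
  expect_error(kymo_spec(line_rate = -1))
  expect_error(kymo_spec(rbc_rate = -2))
  expect_error(kymo_spec(n_lines = 8000, stall_intervals = list(c(0, 5), c(4, 6))),
               "non-overlapping")
  expect_error(kymo_spec(n_lines = 800, stall_intervals = list(c(0, 100))),
               "within")
})

test_that("angio generator produces dynamic contrast only on perfused segments", {
  aspec <- angio_spec(volume_shape = c(32, 32), voxel_size = 2,
                      vessel_segments = list(
                        list(a = c(4, 4), b = c(28, 28), radius_um = 3,
                             perfused = TRUE)),
                      frames_per_timepoint = 24, dynamic_contrast = 0.5,
                      noise_sd = 0.05, seed = 21)
  # all non-perfused: every voxel's temporal variance is ~ noise_sd^2
  s0 <- generate_angio_timeseries(aspec, "t0",
                                  schedule = matrix(FALSE, 1, 1))
  v <- apply(s0$t0, c(2, 3), var)
  expect_lt(abs(mean(v) - 0.05^2), 0.05^2 * 0.2)

  # segment toggled off at timepoint 2: its variance drops to background
  s <- generate_angio_timeseries(aspec, c("t1", "t2"),
                                 schedule = rbind(TRUE, FALSE))
  msk <- attr(s, "mask")
  v1 <- apply(s$t1, c(2, 3), var)
  v2 <- apply(s$t2, c(2, 3), var)
  expect_gt(mean(v1[msk]), 10 * mean(v1[!msk]))
  expect_lt(mean(v2[msk]), 3 * mean(v2[!msk]))

  # dynamic_contrast = 0: angiogram indistinguishable from background
  aspec0 <- angio_spec(volume_shape = c(32, 32), voxel_size = 2,
                       vessel_segments = list(
                         list(a = c(4, 4), b = c(28, 28), radius_um = 3,
                              perfused = TRUE)),
                       frames_per_timepoint = 24, dynamic_contrast = 0,
                       noise_sd = 0.05, seed = 22)
  sz <- generate_angio_timeseries(aspec0, "t0")
  az <- compute_angiogram(sz$t0)
  expect_lt(abs(mean(az$map[msk]) / mean(az$map[!msk]) - 1), 0.1)

  expect_error(angio_spec(vessel_segments = list()), "non-empty")
  expect_error(angio_spec(vessel_segments = list(
    list(a = c(0, 5), b = c(10, 10), radius_um = 2, perfused = TRUE))),
    "inside")
})

test_that("trial-table generator replays exact counts and converges in law", {
  spec <- trial_spec(seed = 3)
  replay <- generate_trial_table(spec, replay = list(
    RoseBengal = c(blockage = 57, hemorrhage = 0),
    FitC = c(blockage = 12, hemorrhage = 0)))
  r <- incidence_rates(replay, "BLOCKAGE")
  expect_equal(r$rate_pct[r$group == "RoseBengal"], 60)
  expect_equal(r$rate_pct[r$group == "FitC"], 100 * 12 / 82, tolerance = 1e-12)

  # zero blockage probability -> zero blockage outcomes
  z <- generate_trial_table(trial_spec(
    blockage_prob = c(RoseBengal = 0, FitC = 0), seed = 4))
  expect_equal(sum(z$outcome == "BLOCKAGE"), 0)

  # law of large numbers at n = 1e4: within 3 binomial SE of p = 0.6
  big <- generate_trial_table(trial_spec(
    n_trials = c(A = 10000L, B = 10L),
    blockage_prob = c(A = 0.6, B = 0.1),
    hemorrhage_prob = c(A = 0.1, B = 0.1), seed = 7))
  phat <- mean(big$outcome[big$group == "A"] == "BLOCKAGE")
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(phat - 0.6), 3 * se)

  # determinism
  t1 <- generate_trial_table(trial_spec(seed = 9))
  t2 <- generate_trial_table(trial_spec(seed = 9))
  expect_identical(t1, t2)
})

test_that("power-sweep generator has the stated order and retains truth", {
  sw <- generate_power_sweep(2, coeff = 4, powers = c(1, 2, 4, 8), noise_sd = 0)
  lp <- log(sw$powers); li <- log(sw$intensities)
  # closed-form least-squares slope (independent of fit_power_slope)
  slope <- sum((lp - mean(lp)) * (li - mean(li))) / sum((lp - mean(lp))^2)
  expect_equal(slope, 2, tolerance = 1e-12)
  sw1 <- generate_power_sweep(1, powers = c(2, 3, 5, 9), noise_sd = 0)
  lp <- log(sw1$powers); li <- log(sw1$intensities)
  slope1 <- sum((lp - mean(lp)) * (li - mean(li))) / sum((lp - mean(lp))^2)
  expect_equal(slope1, 1, tolerance = 1e-12)
  expect_equal(attr(sw, "truth")$order, 2)
  expect_error(generate_power_sweep(2, powers = c(-1, 2, 3)), "positive")
})
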
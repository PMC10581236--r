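test_that("binarization recovers known masks", {
  # two-level image: exact mask
  img <- matrix(0, 20, 20); img[5:8, 3:17] <- 1
  vm <- binarize_angiogram(img)
  expect_equal(vm$mask, img == 1)
  # constant image has no threshold
  expect_error(binarize_angiogram(matrix(1, 5, 5)), "constant")
  # min_size larger than every component: empty mask with a warning
  expect_warning(vm0 <- binarize_angiogram(img, min_size = 1000),
                 "min_size")
  expect_false(any(vm0$mask))
  # own Otsu agrees with the EBImage reference on a 2-D image in [0,1]
  set.seed(60)
  x <- matrix(c(rbeta(200, 2, 8), rbeta(200, 8, 2)), 20, 20)
  expect_equal(otsu_threshold(x),
               EBImage::otsu(EBImage::Image(x)), tolerance = 0.02)
})

test_that("binarized synthetic angiograms overlap ground truth (Dice > 0.8)", {
  spec <- angio_spec(volume_shape = c(40, 40), voxel_size = 2,
                     vessel_segments = list(
                       list(a = c(5, 5), b = c(35, 35), radius_um = 3,
                            perfused = TRUE),
                       list(a = c(5, 35), b = c(35, 5), radius_um = 3,
                            perfused = TRUE)),
                     frames_per_timepoint = 16, dynamic_contrast = 0.5,
                     noise_sd = 0.1, seed = 9)
  series <- generate_angio_timeseries(spec, "t0")
  gt <- attr(series, "mask")
  vm <- binarize_angiogram(compute_angiogram(series$t0), min_size = 5)
  dice <- 2 * sum(vm$mask & gt) / (sum(vm$mask) + sum(gt))
  expect_gt(dice, 0.8)
})

test_that("distance transform is exact against the all-pairs oracle", {
  # analytic case: single vessel voxel at the centre of a 5x5 grid
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  df <- distance_field(m, voxel_size = 1)
  expect_equal(df$distances[1, 1], 2 * sqrt(2))
  expect_equal(df$distances[3, 3], 0)
  expect_equal(df$distances[3, 5], 2)

  # random 3-D masks, isotropic and anisotropic
  set.seed(70)
  for (spacing in list(1, c(1, 1.5, 2))) {
    m3 <- array(runif(16^3) < 0.01, dim = c(16, 16, 16))
    m3[1, 1, 1] <- TRUE
    df3 <- distance_field(m3, voxel_size = spacing)
    expect_equal(df3$distances, brute_force_edt(m3, spacing), tolerance = 1e-9)
  }

  # all-vessel mask: all distances zero
  expect_true(all(distance_field(array(TRUE, c(4, 4)))$distances == 0))
  expect_error(distance_field(array(FALSE, c(4, 4))), "no vessel")
})

test_that("distance histogram conserves the tissue-voxel total", {
  set.seed(71)
  m <- array(runif(20^2) < 0.05, dim = c(20, 20))
  m[1] <- TRUE
  df <- distance_field(m, voxel_size = 2, bin_width = 2)
  expect_equal(sum(df$histogram$counts), sum(!m))
  expect_true(all(df$distances >= 0))
})

test_that("shrinking the vessel set never shortens any distance", {
  set.seed(72)
  A <- array(runif(12^3) < 0.04, dim = c(12, 12, 12))
  A[6, 6, 6] <- TRUE
  B <- A
  drop_idx <- which(A)[seq(1, sum(A), by = 2)]
  B[drop_idx] <- FALSE
  if (!any(B)) B[6, 6, 6] <- TRUE
  dA <- distance_field(A)$distances
  dB <- distance_field(B)$distances
  expect_true(all(dB >= dA - 1e-12))
})

test_that("removing a segment shifts the distance histogram upward", {
  shape <- c(40, 40)
  seg <- function(a, b) list(a = a, b = b, radius_um = 2, perfused = TRUE)
  spec_full <- angio_spec(volume_shape = shape, voxel_size = 2,
                          vessel_segments = list(seg(c(10, 5), c(10, 35)),
                                                 seg(c(30, 5), c(30, 35))),
                          seed = 1)
  masks <- rasterize_vessels(spec_full)$segment_masks
  before <- masks[[1]] | masks[[2]]
  after <- masks[[2]]
  df_b <- distance_field(before, voxel_size = 2)
  df_a <- distance_field(after, voxel_size = 2)
  shift <- compare_distance_fields(df_b, df_a)
  expect_gt(shift$delta_mean_um, 0)
  expect_true(all(df_a$distances >= df_b$distances - 1e-12))

  # identical masks: all deltas exactly zero
  same <- compare_distance_fields(df_b, df_b)
  expect_identical(same$delta_mean_um, 0)
  expect_identical(same$delta_median_um, 0)
  expect_identical(same$delta_p95_um, 0)
  expect_error(compare_distance_fields(df_b, distance_field(matrix(TRUE, 3, 3))),
               "mismatched")
})

test_that("a redundant segment's loss perturbs distances less than an isolated one's", {
  shape <- c(60, 60)
  seg <- function(r1, r2) list(a = c(r1, 5), b = c(r2, 55), radius_um = 2,
                               perfused = TRUE)
  # redundant: target at row 20 with a parallel vessel 2 voxels away (4 µm);
  # isolated: target at row 45 with no close neighbour
  mk <- function(rows) {
    spec <- angio_spec(volume_shape = shape, voxel_size = 2,
                       vessel_segments = lapply(rows, function(r) seg(r, r)),
                       seed = 1)
    rasterize_vessels(spec)$mask
  }
  base_rows <- c(20, 22, 45)
  d_full <- distance_field(mk(base_rows), voxel_size = 2)
  d_no_red <- distance_field(mk(c(22, 45)), voxel_size = 2)   # drop redundant
  d_no_iso <- distance_field(mk(c(20, 22)), voxel_size = 2)   # drop isolated
  s_red <- compare_distance_fields(d_full, d_no_red)
  s_iso <- compare_distance_fields(d_full, d_no_iso)
  expect_lt(s_red$delta_p95_um, s_iso$delta_p95_um)
})
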
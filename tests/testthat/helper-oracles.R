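# Independent oracles used across the suite. Each is a deliberately naive
# computation (brute force / closed form) kept separate from the package's
# own code paths.

# all-pairs nearest-vessel distance (anisotropic), O(N^2)
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  spacing <- rep_len(spacing, length(d))
  pm <- arrayInd(which(mask), d)
  allv <- arrayInd(seq_len(prod(d)), d)
  bf <- apply(allv, 1, function(p) {
    d2 <- rowSums(sweep(pm, 2, p)^2 %*% diag(spacing^2, length(d)))
    sqrt(min(d2))
  })
  array(bf, d)
}

# closed-form pooled two-proportion z (independent re-derivation)
brute_force_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  ph <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
}

# stall intervals from ground-truth passage times by brute-force window scan
brute_force_stalls <- function(entry_s, duration_s, window_s, min_gap_s) {
  edges <- seq(0, duration_s, by = window_s)
  counts <- graphics::hist(entry_s, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  zi <- which(r$values)
  ev <- data.frame(start_s = edges[starts[zi]], end_s = edges[ends[zi] + 1])
  ev$duration_s <- ev$end_s - ev$start_s
  ev[ev$duration_s >= min_gap_s, , drop = FALSE]
}

# hand-built hemodynamic trace (tiled windows)
make_trace <- function(flux, speed, valid = rep(TRUE, length(flux)),
                       window_s = 1) {
  tr <- data.frame(t_s = (seq_along(flux) - 0.5) * window_s,
                   flux_cps = flux, speed_mm_s = speed, valid = valid)
  class(tr) <- c("hemo_trace", "data.frame")
  attr(tr, "window_s") <- window_s
  attr(tr, "step_s") <- window_s
  attr(tr, "duration_s") <- length(flux) * window_s
  tr
}

# brute-force streak slope on a noiseless kymograph: per-row intensity
# minimum centroid, least squares of time on position
trace_streak_slope <- function(kymo) {
  img <- kymo$image
  dark_rows <- which(apply(img, 1, min) < 0.7)
  cen <- vapply(dark_rows, function(r) {
    w <- pmax(1 - img[r, ], 0)
    sum(w * seq_along(w)) / sum(w)
  }, numeric(1))
  t_s <- (dark_rows - 1) / kymo$line_rate
  x_um <- (cen - 0.5) * kymo$pixel_pitch
  unname(stats::coef(stats::lm(t_s ~ x_um))[2])  # s/µm
}
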
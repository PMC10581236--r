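#' Detect RBC passage events in a line-scan kymograph
#'
#' RBC shadows appear as slanted dark streaks on the bright plasma band
#' (rows = time, columns = axial position). Detection proceeds in three
#' steps: (1) per-column median subtraction removes the static intensity
#' profile, (2) the residual at the first two columns (the reference
#' position, axial coordinate 0) is scanned for dark runs deeper than
#' `contrast_threshold` robust SDs below the plasma level — each run is one
#' passage, its entry time the run centre — and (3) the streak orientation is
#' estimated per event by a shear-projection (Radon-style) search: over
#' candidate velocities, shadow mass in a window around the event is
#' projected along the sheared time axis and the velocity maximising the
#' projection's energy concentration wins. Streaks steeper than the slowest
#' candidate velocity are flagged stationary.
#'
#' @param kymo A [kymograph()].
#' @param contrast_threshold Detection depth in robust-SD units, default 3.
#' @param min_run_lines Minimum dark-run length in lines (suppresses
#'   single-line noise hits), default 2.
#' @param speed_range_mm_s Candidate speed magnitudes searched for the streak
#'   orientation, in mm/s.
#' @return Data frame, one row per event: `entry_s`, `slope_s_per_um`
#'   (time per distance, `Inf` for stationary streaks), `speed_mm_s`
#'   (0 for stationary), `stationary`. Empty for a constant image.
#' @export
detect_passages <- function(kymo, contrast_threshold = 3, min_run_lines = 2,
                            speed_range_mm_s = c(0.05, 10)) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  col_med <- apply(img, 2, stats::median)
  resid <- sweep(img, 2, col_med)
  s <- max(stats::mad(resid), 0.01)

  refprof <- rowMeans(resid[, 1:2, drop = FALSE]) / s
  refprof <- stats::filter(refprof, rep(1 / 3, 3), sides = 2)
  refprof[is.na(refprof)] <- 0
  dark <- refprof < -contrast_threshold
  if (!any(dark)) {
    return(data.frame(entry_s = numeric(0), slope_s_per_um = numeric(0),
                      speed_mm_s = numeric(0), stationary = logical(0)))
  }
  r <- rle(as.vector(dark))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run_lines
  starts <- starts[keep]; ends <- ends[keep]

  lr <- kymo$line_rate; pitch <- kymo$pixel_pitch
  # candidate velocities in px/line (log grid, both directions, plus 0)
  v_um_s <- exp(seq(log(speed_range_mm_s[1] * 1000),
                    log(speed_range_mm_s[2] * 1000), length.out = 80))
  v_px <- v_um_s / (pitch * lr)
  cand <- c(0, v_px, -v_px)

  # connected shadow components isolate each streak so that neighbouring
  # passages do not contaminate its orientation estimate
  dark2 <- resid / s < -contrast_threshold
  lab <- EBImage::bwlabel(matrix(as.numeric(dark2), nrow(img), ncol(img)))

  shear_conc <- function(v, rr, cc, wt) {
    mass <- rowsum(wt, round(cc - v * rr))
    sum(mass^2) / sum(mass)^2
  }

  ev <- lapply(seq_along(starts), function(i) {
    mid <- round((starts[i] + ends[i]) / 2)
    entry_s <- (mid - 1) / lr
    run_rows <- starts[i]:ends[i]
    labs <- lab[run_rows, 1:2]
    labs <- labs[labs > 0]
    if (!length(labs)) {
      return(data.frame(entry_s = entry_s, slope_s_per_um = NA_real_,
                        speed_mm_s = NA_real_, stationary = NA))
    }
    id <- as.integer(names(which.max(table(labs))))
    nz <- which(lab == id, arr.ind = TRUE)
    wt <- pmax(-resid[nz] / s - contrast_threshold, 0)
    rr <- nz[, 1] - mid
    cc <- nz[, 2]
    score <- vapply(cand, shear_conc, numeric(1), rr = rr, cc = cc, wt = wt)
    kbest <- which.max(score)
    vbest <- cand[kbest]
    if (vbest != 0) {
      # fine search between the neighbouring coarse candidates
      sgn <- sign(vbest); av <- abs(vbest)
      lo <- av / 1.15; hi <- av * 1.15
      fine <- sgn * seq(lo, hi, length.out = 25)
      fs <- vapply(fine, shear_conc, numeric(1), rr = rr, cc = cc, wt = wt)
      vbest <- fine[which.max(fs)]
    }
    if (vbest == 0) {
      data.frame(entry_s = entry_s, slope_s_per_um = Inf, speed_mm_s = 0,
                 stationary = TRUE)
    } else {
      sp_um_s <- abs(vbest) * pitch * lr
      data.frame(entry_s = entry_s, slope_s_per_um = 1 / sp_um_s,
                 speed_mm_s = sp_um_s / 1000, stationary = FALSE)
    }
  })
  do.call(rbind, ev)
}

#' Windowed RBC flux and speed trace
#'
#' Aggregates detected passages into tiled (or stepped) windows:
#' flux = events per window / window length (cells/s); speed = median of the
#' per-event speeds in the window (mm/s, NA when the window holds no events).
#' A window is flagged invalid when the whole-line plasma level (80th
#' percentile of the line) jumps by more than 25 % between adjacent lines
#' inside it — the signature of an axial sample displacement, which corrupts
#' both flux and speed.
#'
#' @param passages Data frame from [detect_passages()] (or generator truth
#'   with columns `entry_s` and `speed_mm_s`).
#' @param kymo The source [kymograph()].
#' @param window_s Window length in s (>= 2 / line rate).
#' @param step_s Window step; defaults to `window_s` (tiling, which makes
#'   flux exactly conservative: sum(flux * window) = total passages).
#' @param jump_frac Relative adjacent-line median jump that marks a motion
#'   artifact, default 0.25.
#' @return Data frame of class `hemo_trace`: `t_s` (window centres),
#'   `flux_cps`, `speed_mm_s`, `valid`; attributes `window_s`, `step_s`,
#'   `duration_s`.
#' @export
compute_hemo_trace <- function(passages, kymo, window_s = 1,
                               step_s = window_s, jump_frac = 0.25) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!nrow(kymo$image)) stop("empty kymograph")
  if (window_s < 2 / kymo$line_rate)
    stop("window_s must be >= 2 / line_rate")
  duration <- nrow(kymo$image) / kymo$line_rate
  starts <- seq(0, duration - window_s + 1e-12, by = step_s)
  centers <- starts + window_s / 2

  if (is.null(passages$speed_mm_s) && !is.null(passages$slope_s_per_um))
    passages$speed_mm_s <- 1 / passages$slope_s_per_um / 1000
  entry <- passages$entry_s

  # per-line plasma level: upper quantile, so that coincident RBC shadows
  # (which can cover half the columns) do not mimic a whole-line step
  line_lvl <- apply(kymo$image, 1, stats::quantile, probs = 0.8, names = FALSE)
  jumps <- which(abs(diff(line_lvl)) > jump_frac * pmax(abs(line_lvl[-length(line_lvl)]),
                                                        .Machine$double.eps))
  jump_t <- (jumps - 0.5) / kymo$line_rate

  flux <- speed <- numeric(length(starts))
  valid <- logical(length(starts))
  for (i in seq_along(starts)) {
    lo <- starts[i]; hi <- starts[i] + window_s
    inw <- entry >= lo & entry < hi
    flux[i] <- sum(inw) / window_s
    sp <- passages$speed_mm_s[inw]
    sp <- sp[is.finite(sp) & sp > 0]
    speed[i] <- if (length(sp)) stats::median(sp) else NA_real_
    valid[i] <- !any(jump_t >= lo & jump_t < hi)
  }
  tr <- data.frame(t_s = centers, flux_cps = flux, speed_mm_s = speed,
                   valid = valid)
  class(tr) <- c("hemo_trace", "data.frame")
  attr(tr, "window_s") <- window_s
  attr(tr, "step_s") <- step_s
  attr(tr, "duration_s") <- duration
  tr
}

#' Flux-speed correlation over valid windows
#'
#' Pearson correlation and OLS fit of speed on flux over windows that are
#' artifact-free and carry a defined speed. In healthy capillary flow the
#' two stay linearly coupled even at low values; loss of that coupling is
#' itself informative.
#'
#' @param trace A `hemo_trace`.
#' @return List: `r`, `slope`, `intercept`, `n`.
#' @export
correlate_flux_speed <- function(trace) {
  stopifnot(inherits(trace, "hemo_trace"))
  ok <- trace$valid & is.finite(trace$speed_mm_s)
  if (sum(ok) < 5) stop("need at least 5 valid windows with defined speed")
  x <- trace$flux_cps[ok]; y <- trace$speed_mm_s[ok]
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = sum(ok))
}
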
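#' Perfusion-contrast angiogram from a frame stack
#'
#' Separates dynamic (flowing) voxels from static tissue by high-pass
#' temporal filtering: moving scatterers decorrelate the signal frame to
#' frame, so the per-voxel magnitude of the high-pass-filtered temporal
#' signal is large on perfused vessels and near the noise floor elsewhere.
#' Two filters are available: `"first_diff"` (mean absolute first difference
#' along time, the default) and `"rms"` (RMS after subtracting a running
#' temporal mean of width `cutoff_frames`; the full-stack mean when
#' `cutoff_frames` is NULL).
#'
#' @param stack Numeric array, first dimension time (>= 4 frames), remaining
#'   dimensions space.
#' @param method `"first_diff"` or `"rms"`.
#' @param cutoff_frames High-pass window length in frames for `"rms"`.
#' @return Object of class `angiogram`: `map` (non-negative array with the
#'   stack's spatial shape) and `provenance` (filter parameters).
#' @export
compute_angiogram <- function(stack, method = c("first_diff", "rms"),
                              cutoff_frames = NULL) {
  method <- match.arg(method)
  d <- dim(stack)
  if (is.null(d) || length(d) < 2) stop("stack must be an array (time, space...)")
  nf <- d[1]
  if (nf < 4) stop("need at least 4 frames")
  sp <- d[-1]
  flat <- matrix(stack, nf, prod(sp))
  map <- if (method == "first_diff") {
    colMeans(abs(flat[-1, , drop = FALSE] - flat[-nf, , drop = FALSE]))
  } else {
    if (is.null(cutoff_frames) || cutoff_frames >= nf) {
      hp <- sweep(flat, 2, colMeans(flat))
    } else {
      run <- apply(flat, 2, function(x)
        stats::filter(x, rep(1 / cutoff_frames, cutoff_frames), sides = 2))
      hp <- flat - run
      hp[is.na(hp)] <- 0
    }
    sqrt(colMeans(hp^2))
  }
  structure(list(map = array(map, dim = sp),
                 provenance = list(method = method,
                                   cutoff_frames = cutoff_frames,
                                   n_frames = nf)),
            class = "angiogram")
}

.angio_map <- function(x) {
  if (inherits(x, "angiogram")) x$map else x
}

.roi_stats <- function(map, vessel_roi, background_roi) {
  stopifnot(identical(dim(vessel_roi), dim(map)),
            identical(dim(background_roi), dim(map)))
  if (!any(vessel_roi) || !any(background_roi)) stop("ROIs must be non-empty")
  if (any(vessel_roi & background_roi)) stop("ROIs must be disjoint")
  mb <- mean(map[background_roi])
  if (mb == 0) stop("background ROI mean is zero")
  list(norm = mean(map[vessel_roi]) / mb,
       cv_bg = stats::sd(map[background_roi]) / mb)
}

#' Background-normalised stallogram trace
#'
#' For each angiogram in a time series, the mean perfusion-map intensity in
#' the vessel ROI is normalised to the mean in a nearby background ROI. A
#' flowing vessel sits above the baseline of 1; a stalled vessel is
#' statistically indistinguishable from background, so a timepoint is flagged
#' stalled when its normalised intensity falls at or below
#' `1 + k_sigma * CV(background)`.
#'
#' @param angio_series List of [compute_angiogram()] results (or plain maps)
#'   sharing one spatial shape.
#' @param vessel_roi,background_roi Disjoint, non-empty logical masks with
#'   the maps' shape.
#' @param k_sigma Detection threshold in background-CV units, default 2.
#' @param times Numeric timepoints in s; defaults to `seq_along - 1`.
#' @return Data frame of class `stallogram_trace`: `t_s`, `norm_intensity`,
#'   `stalled`.
#' @export
stallogram <- function(angio_series, vessel_roi, background_roi, k_sigma = 2,
                       times = NULL) {
  stopifnot(length(angio_series) >= 1)
  if (is.null(times)) times <- seq_along(angio_series) - 1
  rows <- lapply(seq_along(angio_series), function(i) {
    st <- .roi_stats(.angio_map(angio_series[[i]]), vessel_roi, background_roi)
    data.frame(t_s = times[i], norm_intensity = st$norm,
               stalled = st$norm <= 1 + k_sigma * st$cv_bg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stallogram_trace", "data.frame")
  out
}

#' Track a targeted vessel across longitudinal timepoints
#'
#' Applies the stallogram perfusion criterion to one angiogram per imaging
#' session (e.g. pre-insult, immediately post, 2 h, 4 h, 24 h) and summarises
#' the insult: a vessel is NOT_PERFUSED when its background-normalised
#' intensity is at or below `1 + k_sigma * CV(background)`; the insult is
#' "recovered" at the first PERFUSED timepoint following a NOT_PERFUSED one.
#'
#' @param timepoint_angios Named list of angiograms (labels = timepoints),
#'   length >= 2, consistent spatial shapes (register upstream with
#'   [register_translation()]).
#' @param vessel_roi,background_roi Logical ROI masks shared across
#'   timepoints.
#' @param k_sigma Threshold in background-CV units, default 2.
#' @return List of class `insult_track`: `status` (data frame with
#'   `timepoint`, `norm_intensity`, `perfused`), `insult_detected`,
#'   `onset` (first non-perfused label or NA), `recovered_at` (first
#'   perfused label after onset, or NA if never re-perfused).
#' @export
track_insult <- function(timepoint_angios, vessel_roi, background_roi,
                         k_sigma = 2) {
  stopifnot(length(timepoint_angios) >= 2)
  labels <- names(timepoint_angios)
  if (is.null(labels)) labels <- as.character(seq_along(timepoint_angios))
  shapes <- lapply(timepoint_angios, function(a) dim(.angio_map(a)))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("timepoint angiograms have inconsistent shapes")
  st <- lapply(timepoint_angios, function(a)
    .roi_stats(.angio_map(a), vessel_roi, background_roi))
  norm <- vapply(st, `[[`, numeric(1), "norm")
  perfused <- norm > 1 + k_sigma * vapply(st, `[[`, numeric(1), "cv_bg")
  status <- data.frame(timepoint = labels, norm_intensity = unname(norm),
                       perfused = unname(perfused))
  onset <- which(!perfused)[1]
  recovered_at <- NA_character_
  if (!is.na(onset)) {
    rec <- which(perfused & seq_along(perfused) > onset)[1]
    if (!is.na(rec)) recovered_at <- labels[rec]
  }
  structure(list(status = status,
                 insult_detected = !is.na(onset),
                 onset = if (is.na(onset)) NA_character_ else labels[onset],
                 recovered_at = recovered_at),
            class = "insult_track")
}

#' Translation-only image registration by cross-correlation
#'
#' Estimates the integer shift aligning `mov` onto `ref` as the argmax of
#' their circular cross-correlation (computed by FFT), with shifts wrapped to
#' the centred range. Used to superimpose longitudinal angiograms before
#' reusing ROI masks or comparing distance maps.
#'
#' @param ref,mov Numeric arrays of identical shape (2-D or 3-D).
#' @return Integer vector: the shift to apply to `mov` (per dimension) so it
#'   aligns with `ref`.
#' @export
register_translation <- function(ref, mov) {
  ref <- .angio_map(ref); mov <- .angio_map(mov)
  stopifnot(identical(dim(ref), dim(mov)))
  d <- dim(ref)
  a <- ref - mean(ref); b <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  idx <- arrayInd(which.max(cc), d) - 1L
  shift <- ifelse(idx > d / 2, idx - d, idx)
  as.integer(shift)
}

#' Apply an integer translation to an array
#'
#' @param x Numeric array.
#' @param shift Integer shift per dimension (as returned by
#'   [register_translation()]).
#' @param fill Value for cells vacated by the shift, default 0.
#' @return Shifted array of the same shape.
#' @export
shift_array <- function(x, shift, fill = 0) {
  d <- dim(x)
  stopifnot(length(shift) == length(d))
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { dst[[k]] <- (1 + s):d[k]; src[[k]] <- 1:(d[k] - s) }
    else        { dst[[k]] <- 1:(d[k] + s); src[[k]] <- (1 - s):d[k] }
  }
  out_idx <- as.matrix(expand.grid(dst))
  in_idx <- as.matrix(expand.grid(src))
  out[out_idx] <- x[in_idx]
  out
}
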
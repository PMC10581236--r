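#' Specification of a synthetic line-scan kymograph
#'
#' Describes a line-scan acquisition along a capillary axis together with the
#' red-blood-cell (RBC) traffic to be drawn into it. Defaults emulate the
#' in-vivo acquisition geometry used for targeted photothrombosis monitoring:
#' repeated line scans at 800 Hz over ~15 µm of vessel axis, with RBCs
#' appearing as slanted dark shadows on a bright plasma band.
#'
#' @param line_rate Line-scan rate in Hz (> 0). Default 800.
#' @param n_lines Number of scanned lines (rows of the kymograph).
#' @param segment_length Scanned length along the vessel axis in µm. Default 15.
#' @param pixel_pitch Spatial sampling in µm/pixel. Default 0.15.
#' @param rbc_rate Mean RBC arrival rate in cells/s (>= 0); arrivals follow a
#'   homogeneous Poisson process thinned to zero inside stall intervals.
#' @param rbc_speed Mean RBC speed in mm/s (> 0).
#' @param rbc_speed_cv Coefficient of variation of per-cell speeds
#'   (log-normal); 0 gives identical speeds.
#' @param shadow_width RBC shadow width along the axis in µm.
#' @param stall_intervals List of `c(start_s, end_s)` no-flow intervals;
#'   must be non-overlapping and lie within the trace.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the plasma
#'   intensity (plasma = 1.0).
#' @param artifacts List of `c(time_s, duration_s, gain)` whole-line intensity
#'   steps emulating axial motion artifacts (lines within the interval are
#'   multiplied by `gain`).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `kymo_spec`.
#' @export
kymo_spec <- function(line_rate = 800, n_lines = 8000, segment_length = 15,
                      pixel_pitch = 0.15, rbc_rate = 10, rbc_speed = 1,
                      rbc_speed_cv = 0.2, shadow_width = 4,
                      stall_intervals = list(), noise_sd = 0.05,
                      artifacts = list(), seed = 1L) {
  stopifnot(line_rate > 0, n_lines >= 1, segment_length > 0, pixel_pitch > 0,
            rbc_speed > 0, rbc_speed_cv >= 0, shadow_width > 0, noise_sd >= 0)
  if (rbc_rate < 0) stop("rbc_rate must be >= 0")
  duration <- n_lines / line_rate
  if (length(stall_intervals)) {
    iv <- do.call(rbind, lapply(stall_intervals, function(s) {
      stopifnot(length(s) == 2, s[2] > s[1])
      s
    }))
    if (any(iv < 0) || any(iv > duration))
      stop("stall intervals must lie within [0, n_lines/line_rate]")
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("stall intervals must be non-overlapping")
  }
  structure(list(line_rate = line_rate, n_lines = as.integer(n_lines),
                 segment_length = segment_length, pixel_pitch = pixel_pitch,
                 rbc_rate = rbc_rate, rbc_speed = rbc_speed,
                 rbc_speed_cv = rbc_speed_cv, shadow_width = shadow_width,
                 stall_intervals = stall_intervals, noise_sd = noise_sd,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "kymo_spec")
}

#' Kymograph container
#'
#' Axis convention (used by every reader and writer in the package):
#' rows = time, one row per scanned line; columns = position along the
#' vessel axis, column 1 at axial coordinate 0.
#'
#' @param image Numeric matrix, rows = time, cols = position (>= 16 columns).
#' @param line_rate Line rate in Hz.
#' @param pixel_pitch µm per pixel along the axis.
#' @param metadata Optional named list (depth_um, power_mW, ...).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(image, line_rate, pixel_pitch, metadata = list()) {
  stopifnot(is.matrix(image), line_rate > 0, pixel_pitch > 0)
  if (ncol(image) < 16) stop("kymograph needs >= 16 position columns")
  structure(list(image = image, line_rate = line_rate,
                 pixel_pitch = pixel_pitch, metadata = metadata),
            class = "kymograph")
}

# shadow contrast relative to plasma (plasma intensity 1.0); edge blur is one
# pixel (Gaussian sigma), both free generator parameters chosen for a
# realistic-looking SNR -- not calibrated to any particular recording.
.SHADOW_CONTRAST <- 0.6
.PLASMA <- 1.0

#' Generate a synthetic line-scan kymograph with ground truth
#'
#' Draws RBC passages as slanted dark streaks (slope = 1/speed in time per
#' distance) over a bright plasma band. Passage entry times (cell centre
#' crossing axial position 0) follow a homogeneous Poisson process, thinned to
#' zero inside the spec's stall intervals; per-cell speeds are log-normal.
#'
#' @param spec A [kymo_spec()].
#' @return A [kymograph()] whose `truth` attribute is a data frame with one
#'   row per passage (`entry_s`, `speed_mm_s`), and whose `spec` attribute is
#'   the generating spec.
#' @export
generate_kymograph <- function(spec) {
  stopifnot(inherits(spec, "kymo_spec"))
  withr::with_seed(spec$seed, .generate_kymograph(spec))
}

.generate_kymograph <- function(spec) {
  duration <- spec$n_lines / spec$line_rate
  n_cols <- max(16L, as.integer(round(spec$segment_length / spec$pixel_pitch)))
  n <- stats::rpois(1, spec$rbc_rate * duration)
  entry <- sort(stats::runif(n, 0, duration))
  for (iv in spec$stall_intervals)
    entry <- entry[entry <= iv[1] | entry >= iv[2]]
  m <- spec$rbc_speed * 1000 # µm/s
  if (spec$rbc_speed_cv > 0) {
    sdl <- sqrt(log(1 + spec$rbc_speed_cv^2))
    speeds <- stats::rlnorm(length(entry), log(m) - sdl^2 / 2, sdl)
  } else speeds <- rep(m, length(entry))

  img <- matrix(.PLASMA, spec$n_lines, n_cols)
  xp <- (seq_len(n_cols) - 0.5) * spec$pixel_pitch        # column centres, µm
  sig <- spec$pixel_pitch                                  # 1-pixel edge blur
  half <- spec$shadow_width / 2
  t_row <- (seq_len(spec$n_lines) - 1) / spec$line_rate
  for (i in seq_along(entry)) {
    v <- speeds[i]
    # rows over which the shadow (centre position v*(t-t0)) intersects the
    # scanned segment, padded by half-width + 3 sigma of blur
    pad <- (half + 3 * sig) / v
    rows <- which(t_row >= entry[i] - pad &
                  t_row <= entry[i] + (max(xp) + half + 3 * sig) / v)
    if (!length(rows)) next
    xc <- v * (t_row[rows] - entry[i])
    depth <- .SHADOW_CONTRAST *
      (stats::pnorm(outer(xc + half, xp, "-") / sig) -
       stats::pnorm(outer(xc - half, xp, "-") / sig))
    img[rows, ] <- img[rows, ] * (1 - depth)
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  for (a in spec$artifacts) {
    rows <- which(t_row >= a[1] & t_row < a[1] + a[2])
    gain <- if (length(a) >= 3) a[3] else 1.5
    img[rows, ] <- img[rows, ] * gain
  }
  k <- kymograph(img, spec$line_rate, spec$pixel_pitch)
  attr(k, "truth") <- data.frame(entry_s = entry, speed_mm_s = speeds / 1000)
  attr(k, "spec") <- spec
  k
}

#' Specification of a synthetic angiogram time series
#'
#' Describes a voxel grid holding a set of capillary segments (capsules:
#' cylinders with hemispherical caps) and the temporal statistics of the
#' frame stacks recorded over it. Perfused segments fluctuate frame to frame
#' (moving scatterers); blocked segments and background are static up to the
#' detection noise, mirroring label-free angiography in which a blocked
#' vessel becomes indistinguishable from tissue.
#'
#' @param volume_shape Integer vector of 2 (y, x) or 3 (z, y, x) voxel counts.
#' @param voxel_size Voxel size in µm (scalar, or one value per dimension).
#' @param vessel_segments List of segments, each a list with `a`, `b`
#'   (endpoint coordinates in voxel units, inside the volume), `radius_um`
#'   (> 0) and `perfused` (logical baseline flag).
#' @param frames_per_timepoint Frames recorded per timepoint (>= 4).
#' @param dynamic_contrast SD of the frame-to-frame intensity fluctuation on
#'   perfused voxels (dimensionless, relative to the static base of 1).
#' @param noise_sd SD of the static detection noise everywhere.
#' @param seed Integer seed.
#' @return An object of class `angio_spec`.
#' @export
angio_spec <- function(volume_shape = c(48L, 48L), voxel_size = 2,
                       vessel_segments, frames_per_timepoint = 16L,
                       dynamic_contrast = 0.5, noise_sd = 0.05, seed = 1L) {
  stopifnot(length(volume_shape) %in% c(2L, 3L), all(volume_shape >= 4),
            all(voxel_size > 0), frames_per_timepoint >= 4,
            dynamic_contrast >= 0, noise_sd >= 0)
  if (!length(vessel_segments)) stop("vessel_segments must be non-empty")
  nd <- length(volume_shape)
  for (s in vessel_segments) {
    stopifnot(length(s$a) == nd, length(s$b) == nd, s$radius_um > 0)
    if (any(s$a < 1) || any(s$a > volume_shape) ||
        any(s$b < 1) || any(s$b > volume_shape))
      stop("segment endpoints must lie inside the volume")
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size = rep_len(voxel_size, nd),
                 vessel_segments = vessel_segments,
                 frames_per_timepoint = as.integer(frames_per_timepoint),
                 dynamic_contrast = dynamic_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "angio_spec")
}

# logical mask of voxels within radius of the segment (capsule rasterization)
.rasterize_segment <- function(shape, voxel_size, a, b, radius_um) {
  nd <- length(shape)
  grids <- lapply(seq_len(nd), function(d) (seq_len(shape[d]) - 0.5) * voxel_size[d])
  coords <- as.matrix(expand.grid(grids))
  pa <- (a - 0.5) * voxel_size
  pb <- (b - 0.5) * voxel_size
  ab <- pb - pa
  denom <- sum(ab^2)
  diffm <- sweep(coords, 2, pa)
  tt <- if (denom == 0) rep(0, nrow(coords)) else
    pmin(1, pmax(0, as.vector(diffm %*% ab) / denom))
  proj <- sweep(tt %o% ab, 2, pa, "+")
  d2 <- rowSums((coords - proj)^2)
  array(d2 <= radius_um^2, dim = shape)
}

#' Rasterize the vessel segments of an angio spec
#'
#' @param spec An [angio_spec()].
#' @return List with per-segment logical masks (`segment_masks`) and their
#'   union (`mask`), on the spec's voxel grid.
#' @export
rasterize_vessels <- function(spec) {
  stopifnot(inherits(spec, "angio_spec"))
  masks <- lapply(spec$vessel_segments, function(s)
    .rasterize_segment(spec$volume_shape, spec$voxel_size, s$a, s$b, s$radius_um))
  total <- Reduce(`|`, masks)
  list(segment_masks = masks, mask = total)
}

#' Generate frame stacks across longitudinal timepoints
#'
#' Produces one frame stack per timepoint. Each stack holds
#' `frames_per_timepoint` frames of a static base image (tissue and vessel
#' structure both at intensity 1) plus detection noise; voxels belonging to a
#' segment that is perfused at that timepoint additionally fluctuate frame to
#' frame with SD `dynamic_contrast`. The perfusion schedule is the ground
#' truth for stallogram and tracking tests.
#'
#' @param spec An [angio_spec()].
#' @param timepoints Character vector of timepoint labels.
#' @param schedule Logical matrix, `length(timepoints)` rows x one column per
#'   segment: is the segment perfused at that timepoint? Defaults to each
#'   segment's baseline `perfused` flag at every timepoint.
#' @return Named list of stacks (each an array `(frame, y, x[, z])`-free:
#'   dims are `c(frames, volume_shape)`), with attributes `schedule`,
#'   `segment_masks`, `mask`, and `spec`.
#' @export
generate_angio_timeseries <- function(spec, timepoints, schedule = NULL) {
  stopifnot(inherits(spec, "angio_spec"), length(timepoints) >= 1)
  nseg <- length(spec$vessel_segments)
  if (is.null(schedule)) {
    base <- vapply(spec$vessel_segments, function(s) isTRUE(s$perfused), logical(1))
    schedule <- matrix(base, length(timepoints), nseg, byrow = TRUE)
  }
  stopifnot(is.matrix(schedule), nrow(schedule) == length(timepoints),
            ncol(schedule) == nseg)
  ras <- rasterize_vessels(spec)
  out <- withr::with_seed(spec$seed, {
    lapply(seq_along(timepoints), function(ti) {
      nf <- spec$frames_per_timepoint
      dims <- c(nf, spec$volume_shape)
      frames <- array(1, dims)
      if (spec$noise_sd > 0)
        frames <- frames + stats::rnorm(prod(dims), 0, spec$noise_sd)
      if (spec$dynamic_contrast > 0) {
        for (si in seq_len(nseg)) {
          if (!schedule[ti, si]) next
          vox <- which(ras$segment_masks[[si]])
          fluc <- matrix(stats::rnorm(nf * length(vox), 0, spec$dynamic_contrast),
                         nf, length(vox))
          idx <- cbind(rep(seq_len(nf), length(vox)),
                       arrayInd(rep(vox, each = nf), spec$volume_shape))
          frames[idx] <- frames[idx] + as.vector(t(fluc))
        }
      }
      frames
    })
  })
  names(out) <- timepoints
  attr(out, "schedule") <- schedule
  attr(out, "segment_masks") <- ras$segment_masks
  attr(out, "mask") <- ras$mask
  attr(out, "spec") <- spec
  out
}

#' Specification of a synthetic photothrombosis trial table
#'
#' Two-group Bernoulli trial design: each trial yields one categorical
#' outcome (BLOCKAGE, HEMORRHAGE or NONE) at a depth drawn from the stated
#' levels and an excitation duration drawn from a truncated normal.
#' Defaults emulate a Rose Bengal photosensitizer group versus a fluorescein
#' (FitC) control at the observed incidence rates and a ~300 s mean
#' excitation time.
#'
#' @param n_trials Named integer vector of trials per group.
#' @param blockage_prob Named numeric vector in `[0,1]` per group.
#' @param hemorrhage_prob Named numeric vector in `[0,1]` per group;
#'   `blockage_prob + hemorrhage_prob <= 1` per group.
#' @param depth_levels Depth levels in µm below the pia.
#' @param excitation_mean,excitation_sd Mean and SD (s) of the excitation
#'   duration (normal truncated at 0).
#' @param seed Integer seed.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_trials = c(RoseBengal = 95L, FitC = 82L),
                       blockage_prob = c(RoseBengal = 0.60, FitC = 12 / 82),
                       hemorrhage_prob = c(RoseBengal = 0.10, FitC = 0.10),
                       depth_levels = c(100, 150, 200),
                       excitation_mean = 300, excitation_sd = 225,
                       seed = 1L) {
  groups <- names(n_trials)
  stopifnot(!is.null(groups), all(nzchar(groups)),
            identical(groups, names(blockage_prob)),
            identical(groups, names(hemorrhage_prob)),
            all(n_trials >= 1),
            all(blockage_prob >= 0), all(blockage_prob <= 1),
            all(hemorrhage_prob >= 0), all(hemorrhage_prob <= 1),
            all(blockage_prob + hemorrhage_prob <= 1),
            excitation_mean > 0, excitation_sd >= 0)
  structure(list(n_trials = n_trials, blockage_prob = blockage_prob,
                 hemorrhage_prob = hemorrhage_prob,
                 depth_levels = depth_levels,
                 excitation_mean = excitation_mean,
                 excitation_sd = excitation_sd, seed = as.integer(seed)),
            class = "trial_spec")
}

.OUTCOMES <- c("BLOCKAGE", "HEMORRHAGE", "NONE")

#' Generate (or replay) a trial table
#'
#' In sampling mode, outcomes are drawn per trial from the spec's
#' probabilities. In replay mode, exact per-group outcome counts are emitted
#' deterministically (outcomes ordered BLOCKAGE, HEMORRHAGE, NONE within each
#' group), which reproduces a recorded contingency table instead of sampling
#' around it.
#'
#' @param spec A [trial_spec()].
#' @param replay Optional named list: per group, `c(blockage = k, hemorrhage = m)`
#'   exact counts. When supplied, no outcome sampling occurs.
#' @return Data frame with columns `group`, `outcome`, `depth_um`,
#'   `excitation_s` (class `trial_table`).
#' @export
generate_trial_table <- function(spec, replay = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  groups <- names(spec$n_trials)
  withr::with_seed(spec$seed, {
    rows <- lapply(groups, function(g) {
      n <- spec$n_trials[[g]]
      if (is.null(replay)) {
        u <- stats::runif(n)
        pb <- spec$blockage_prob[[g]]
        ph <- spec$hemorrhage_prob[[g]]
        outcome <- ifelse(u < pb, "BLOCKAGE",
                          ifelse(u < pb + ph, "HEMORRHAGE", "NONE"))
      } else {
        k <- replay[[g]]
        kb <- if ("blockage" %in% names(k)) k[["blockage"]] else 0L
        kh <- if ("hemorrhage" %in% names(k)) k[["hemorrhage"]] else 0L
        stopifnot(kb + kh <= n)
        outcome <- rep(c("BLOCKAGE", "HEMORRHAGE", "NONE"),
                       c(kb, kh, n - kb - kh))
      }
      depth <- sample(spec$depth_levels, n, replace = TRUE)
      exc <- stats::rnorm(n, spec$excitation_mean, spec$excitation_sd)
      while (any(exc <= 0))
        exc[exc <= 0] <- stats::rnorm(sum(exc <= 0), spec$excitation_mean,
                                      spec$excitation_sd)
      data.frame(group = g, outcome = outcome, depth_um = depth,
                 excitation_s = exc)
    })
    tab <- do.call(rbind, rows)
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

#' Generate a synthetic excitation power sweep
#'
#' Emulates a dye photophysics characterisation: fluorescence intensity
#' follows `coeff * P^order`, with optional multiplicative Gaussian noise.
#' The generating order is retained for recovery tests.
#'
#' @param order True excitation order (> 0); 2 for a two-photon process.
#' @param coeff Positive scale coefficient.
#' @param powers Excitation powers in mW (all > 0, length >= 3).
#' @param noise_sd SD of the multiplicative noise `(1 + eps)`.
#' @param wavelength_nm Excitation wavelength recorded in the sweep.
#' @param seed Integer seed.
#' @return A [power_sweep()] with attribute `truth = list(order, coeff)`.
#' @export
generate_power_sweep <- function(order, coeff = 1, powers, noise_sd = 0,
                                 wavelength_nm = 1000, seed = 1L) {
  stopifnot(order > 0, coeff > 0, noise_sd >= 0)
  if (any(powers <= 0)) stop("powers must be strictly positive")
  intens <- withr::with_seed(seed, {
    coeff * powers^order * (1 + stats::rnorm(length(powers), 0, noise_sd))
  })
  if (any(intens <= 0)) intens <- pmax(intens, .Machine$double.eps)
  sw <- power_sweep(powers, intens, wavelength_nm)
  attr(sw, "truth") <- list(order = order, coeff = coeff)
  sw
}
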
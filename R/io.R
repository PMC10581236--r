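#' @keywords internal
#' Shared TIFF helpers. The tiff package stores samples in [0, 1], so arrays
#' are affinely rescaled on write and the (offset, scale) pair recorded in
#' the JSON sidecar; round-trip is exact to float32 precision.
.tiff_scale <- function(x) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  list(data = (x - lo) / scale, offset = lo, scale = scale)
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for ", path, " (expected ", sp, ")")
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a kymograph as float32 TIFF plus JSON sidecar
#'
#' Axis convention in the file: rows = time (one row per scanned line),
#' columns = axial position. The sidecar carries `line_rate`, `pixel_pitch`,
#' metadata, the intensity rescaling, and — when present — the generator's
#' ground-truth passage list.
#'
#' @param kymo A [kymograph()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  sc <- .tiff_scale(kymo$image)
  tiff::writeTIFF(sc$data, path, bits.per.sample = 32)
  meta <- list(type = "kymograph", axis_order = "rows=time, cols=position",
               line_rate_hz = kymo$line_rate,
               pixel_pitch_um = kymo$pixel_pitch,
               metadata = kymo$metadata,
               intensity_offset = sc$offset, intensity_scale = sc$scale)
  truth <- attr(kymo, "truth")
  if (!is.null(truth)) meta$truth <- truth
  .write_sidecar(path, meta)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' Errors (rather than defaulting) when the JSON sidecar is missing or does
#' not describe a kymograph.
#'
#' @param path TIFF path.
#' @return A [kymograph()], with `truth` attribute if the sidecar holds one.
#' @export
read_kymograph <- function(path) {
  meta <- .read_sidecar(path)
  if (!identical(meta$type, "kymograph"))
    stop("sidecar does not describe a kymograph: ", path)
  img <- tiff::readTIFF(path)
  img <- img * meta$intensity_scale + meta$intensity_offset
  k <- kymograph(img, meta$line_rate_hz, meta$pixel_pitch_um,
                 as.list(meta$metadata))
  if (!is.null(meta$truth)) attr(k, "truth") <- as.data.frame(meta$truth)
  k
}

#' Write a frame stack as multi-page float32 TIFF plus JSON sidecar
#'
#' @param stack Numeric array `(time, y, x)`; one TIFF page per frame.
#' @param path Output TIFF path.
#' @param frame_interval_s Frame interval in s.
#' @param voxel_size_um Voxel size in µm (scalar or per spatial dimension).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, frame_interval_s = 1,
                              voxel_size_um = 1) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  sc <- .tiff_scale(stack)
  pages <- lapply(seq_len(d[1]), function(i) sc$data[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  .write_sidecar(path, list(type = "frame_stack",
                            axis_order = "(time, y, x), 0-based, row-major",
                            n_frames = d[1],
                            frame_interval_s = frame_interval_s,
                            voxel_size_um = voxel_size_um,
                            intensity_offset = sc$offset,
                            intensity_scale = sc$scale))
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path.
#' @return Array `(time, y, x)` with attributes `frame_interval_s`,
#'   `voxel_size_um`.
#' @export
read_frame_stack <- function(path) {
  meta <- .read_sidecar(path)
  if (!identical(meta$type, "frame_stack"))
    stop("sidecar does not describe a frame stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_frames)
    stop("frame count mismatch between TIFF (", length(pages),
         ") and sidecar (", meta$n_frames, ")")
  stack <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) stack[i, , ] <- pages[[i]]
  stack <- stack * meta$intensity_scale + meta$intensity_offset
  attr(stack, "frame_interval_s") <- meta$frame_interval_s
  attr(stack, "voxel_size_um") <- meta$voxel_size_um
  stack
}

#' Write a trial table as CSV
#'
#' Header: `group,outcome,depth_um,excitation_s`.
#'
#' @param table Trial table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(all(c("group", "outcome", "depth_um", "excitation_s") %in%
                  names(table)))
  utils::write.csv(table[, c("group", "outcome", "depth_um", "excitation_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table CSV, validating the outcome vocabulary
#'
#' @param path CSV path with header `group,outcome,depth_um,excitation_s`.
#' @return Trial table data frame (class `trial_table`).
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "outcome", "depth_um", "excitation_s")
  if (!all(need %in% names(tab)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$outcome), .OUTCOMES)
  if (length(bad))
    stop("out-of-vocabulary outcome label(s): ", paste(bad, collapse = ", "))
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write a hemodynamic trace as CSV
#'
#' Header: `t_s,flux_cps,speed_mm_s,valid`.
#'
#' @param trace A `hemo_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hemo_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hemo_trace"))
  df <- as.data.frame(trace)
  df$window_s <- attr(trace, "window_s")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a hemodynamic trace CSV
#'
#' @param path CSV path written by [write_hemo_trace()].
#' @return A `hemo_trace`.
#' @export
read_hemo_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "flux_cps", "speed_mm_s", "valid", "window_s")
  if (!all(need %in% names(df)))
    stop("hemo trace must have columns: ", paste(need, collapse = ", "))
  w <- df$window_s[1]
  tr <- df[, c("t_s", "flux_cps", "speed_mm_s", "valid")]
  class(tr) <- c("hemo_trace", "data.frame")
  attr(tr, "window_s") <- w
  attr(tr, "step_s") <- if (nrow(tr) > 1) diff(tr$t_s[1:2]) else w
  attr(tr, "duration_s") <- tr$t_s[nrow(tr)] + w / 2
  tr
}

#' Read a power sweep CSV
#'
#' @param path CSV with columns `power_mW,intensity`.
#' @param wavelength Wavelength (nm) to record on the sweep.
#' @return A [power_sweep()].
#' @export
read_power_sweep <- function(path, wavelength = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("power_mW", "intensity") %in% names(df)))
    stop("power sweep CSV must have columns power_mW,intensity")
  power_sweep(df$power_mW, df$intensity, wavelength)
}

#' Write ROI polygons as JSON
#'
#' Vertices are stored 0-based in pixel coordinates, row-major `(row, col)`.
#'
#' @param rois Named list of polygons, each an n x 2 matrix of `(row, col)`
#'   vertices (1-based in R; written 0-based).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2)
    unname(p - 1)
  })
  jsonlite::write_json(list(coordinates = "0-based, row-major (row, col)",
                            rois = out), path, digits = NA)
  invisible(path)
}

#' Read ROI polygons from JSON
#'
#' @param path JSON path written by [write_rois()].
#' @return Named list of n x 2 vertex matrices (1-based `(row, col)`).
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(j$rois, function(p) matrix(p, ncol = 2) + 1)
}

#' Rasterize a polygon ROI into a logical mask
#'
#' Even-odd (ray casting) point-in-polygon test on pixel centres.
#'
#' @param vertices n x 2 matrix of `(row, col)` polygon vertices (1-based).
#' @param dim Target mask dimensions `c(nrow, ncol)`.
#' @return Logical matrix of shape `dim`.
#' @export
roi_polygon_mask <- function(vertices, dim) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3, length(dim) == 2)
  pts <- as.matrix(expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2])))
  nv <- nrow(v)
  inside <- rep(FALSE, nrow(pts))
  j <- nv
  for (i in seq_len(nv)) {
    yi <- v[i, 1]; xi <- v[i, 2]
    yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > pts[, 1]) != (yj > pts[, 1])) &
      (pts[, 2] < (xj - xi) * (pts[, 1] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, dim[1], dim[2])
}
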
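#' Binarize an angiogram into a vessel mask
#'
#' Global Otsu threshold over all voxels (the default), followed by removal
#' of connected components smaller than `min_size` voxels
#' (8/26-connectivity). A fixed numeric threshold may be supplied instead.
#'
#' @param angio An [compute_angiogram()] result or a numeric array.
#' @param method `"otsu"` or a numeric threshold.
#' @param min_size Minimum connected-component size in voxels kept, default 0.
#' @param voxel_size Voxel size in µm (scalar or per-dimension), stored on
#'   the mask.
#' @return Object of class `vessel_mask`: `mask` (logical array),
#'   `voxel_size`, `threshold`.
#' @export
binarize_angiogram <- function(angio, method = "otsu", min_size = 0,
                               voxel_size = 1) {
  x <- .angio_map(angio)
  if (length(unique(as.vector(x))) == 1)
    stop("constant image: no threshold exists")
  thr <- if (is.numeric(method)) method else otsu_threshold(x)
  mask <- x > thr
  if (min_size > 0 && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    mask <- array(lab %in% keep, dim = dim(mask))
    if (!any(mask)) warning("all components smaller than min_size: empty mask")
  }
  structure(list(mask = mask,
                 voxel_size = rep_len(voxel_size, length(dim(x))),
                 threshold = thr),
            class = "vessel_mask")
}

#' Global Otsu threshold
#'
#' Maximises between-class variance over a 256-level histogram of all array
#' values. Operates on arrays of any dimensionality with a single global
#' threshold.
#'
#' @param x Numeric array.
#' @param levels Number of histogram levels, default 256.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: no threshold exists")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Label connected components of a binary array
#'
#' 2-D arrays use `EBImage::bwlabel`; 3-D arrays are labelled through the
#' 6-neighbour voxel adjacency graph.
#'
#' @param mask Logical array (2-D or 3-D).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), d[1], d[2]))
    return(array(as.integer(lab), dim = d))
  }
  stopifnot(length(d) == 3)
  vox <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(vox)) return(lab)
  pos <- arrayInd(vox, d)
  id <- seq_along(vox)
  key <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- integer(prod(d)); lookup[key] <- id
  edges <- NULL
  for (ax in 1:3) {
    nb <- pos; nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nkey <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    nid <- lookup[nkey]
    hit <- nid > 0
    if (any(hit)) edges <- rbind(edges, cbind(id[ok][hit], nid[hit]))
  }
  g <- igraph::graph_from_edgelist(if (is.null(edges)) matrix(0L, 0, 2) else edges,
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[vox] <- as.integer(comp)
  lab
}

# 1-D squared distance transform (lower envelope of parabolas) with sample
# spacing s; f holds squared distances, large-finite standing in for +Inf.
.dt1d <- function(f, s) {
  n <- length(f)
  if (n == 1) return(f)
  x <- seq_len(n) * s
  v <- integer(n); z <- numeric(n + 1)
  k <- 1; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      sx <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (sx <= z[k]) { k <- k - 1 } else break
    }
    k <- k + 1
    v[k] <- q
    z[k] <- sx
    z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1
  for (q in 1:n) {
    while (z[k + 1] < x[q]) k <- k + 1
    p <- v[k]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}

.edt_squared <- function(seed_sq, spacing) {
  d <- dim(seed_sq); nd <- length(d)
  g <- seed_sq
  for (ax in seq_len(nd)) {
    others <- setdiff(seq_len(nd), ax)
    g <- apply(g, others, .dt1d, s = spacing[ax])
    dim(g) <- c(d[ax], d[others])
    g <- aperm(g, match(seq_len(nd), c(ax, others)))
  }
  g
}

#' Euclidean distance to the nearest vessel voxel
#'
#' Exact (anisotropic) Euclidean distance transform of the complement of the
#' vessel mask, computed by the separable lower-envelope algorithm on squared
#' distances. Distances are measured between voxel centres and reported in
#' µm; vessel voxels have distance 0 and are excluded from the histogram
#' domain (tissue voxels only).
#'
#' @param mask A `vessel_mask` (or logical array plus `voxel_size`).
#' @param voxel_size Voxel size in µm when `mask` is a plain array; scalar or
#'   one value per dimension (anisotropic grids allowed).
#' @param bin_width Histogram bin width in µm, default 2.
#' @return Object of class `distance_field`: `distances` (array, µm),
#'   `histogram` (`edges`, `counts` over tissue voxels), `domain` (logical
#'   tissue mask), `voxel_size`, `bin_width`.
#' @export
distance_field <- function(mask, voxel_size = 1, bin_width = 2) {
  if (inherits(mask, "vessel_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  d <- dim(mask)
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim = d)
  if (!any(mask)) stop("mask has no vessel voxel")
  spacing <- rep_len(voxel_size, length(d))
  big <- (sum(d * spacing))^2 * 4
  seed_sq <- array(big, dim = d)
  seed_sq[mask] <- 0
  dist <- sqrt(.edt_squared(seed_sq, spacing))
  domain <- !mask
  dv <- dist[domain]
  edges <- seq(0, max(bin_width, ceiling(max(dv, 0) / bin_width) * bin_width),
               by = bin_width)
  counts <- if (length(dv)) {
    graphics::hist(dv, breaks = edges, plot = FALSE,
                   right = FALSE, include.lowest = TRUE)$counts
  } else integer(length(edges) - 1)
  structure(list(distances = dist,
                 histogram = list(edges = edges, counts = counts),
                 domain = domain, voxel_size = spacing,
                 bin_width = bin_width),
            class = "distance_field")
}

#' Compare two distance fields before and after an occlusion
#'
#' Signed differences (after - before) of the mean, median and 95th
#' percentile of tissue-to-nearest-vessel distances, plus the two histograms
#' rebinned onto shared edges. Positive deltas mean longer distances after —
#' the signature of a lost perfused segment. Grids must match (register
#' upstream).
#'
#' @param before,after `distance_field` objects on identical grids with the
#'   same bin width.
#' @return List of class `distance_shift`: `delta_mean_um`,
#'   `delta_median_um`, `delta_p95_um`, and `histograms` (shared `edges`,
#'   `before`, `after` counts).
#' @export
compare_distance_fields <- function(before, after) {
  stopifnot(inherits(before, "distance_field"), inherits(after, "distance_field"))
  if (!identical(dim(before$distances), dim(after$distances)))
    stop("distance fields are on mismatched grids")
  if (before$bin_width != after$bin_width)
    stop("distance fields use different histogram binning")
  stat <- function(f) {
    v <- f$distances[f$domain]
    c(mean = mean(v), median = stats::median(v),
      p95 = unname(stats::quantile(v, 0.95)))
  }
  sb <- stat(before); sa <- stat(after)
  bw <- before$bin_width
  hi <- max(before$histogram$edges, after$histogram$edges)
  edges <- seq(0, hi, by = bw)
  rebin <- function(f) {
    graphics::hist(f$distances[f$domain], breaks = edges, plot = FALSE,
                   right = FALSE, include.lowest = TRUE)$counts
  }
  structure(list(delta_mean_um = unname(sa["mean"] - sb["mean"]),
                 delta_median_um = unname(sa["median"] - sb["median"]),
                 delta_p95_um = unname(sa["p95"] - sb["p95"]),
                 histograms = list(edges = edges, before = rebin(before),
                                   after = rebin(after))),
            class = "distance_shift")
}
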
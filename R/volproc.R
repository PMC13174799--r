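#' Segmentation parameters
#'
#' Bundles the surface-generation parameters of the 3D workflow. Defaults
#' reproduce the published settings: rolling-ball background subtraction at
#' 37.1 um, Gaussian smoothing of width (sigma) 0.129 um, and exclusion of
#' objects smaller than 121 voxels. The proprietary trained pixel classifier
#' of the original workflow is replaced by transparent thresholding (Otsu by
#' default, or a fixed value); every pipeline output records this
#' substitution in its provenance.
#'
#' @param background_radius rolling-ball radius in um (> 0).
#' @param smoothing_width Gaussian sigma in um (> 0). The published "width"
#'   is interpreted as sigma, not FWHM; pass
#'   `smoothing_width = 0.129 * ...` yourself for other conventions.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param threshold_value intensity cutoff, required when
#'   `threshold = "fixed"`.
#' @param connectivity 26 (faces, edges and corners; default, so diagonal
#'   network contacts join) or 6 (faces only).
#' @param min_voxels strict lower size cutoff: objects with fewer than
#'   `min_voxels` voxels are removed, objects with exactly `min_voxels`
#'   are retained.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(background_radius = 37.1,
                                smoothing_width = 0.129,
                                threshold = c("otsu", "fixed"),
                                threshold_value = NULL,
                                connectivity = 26L,
                                min_voxels = 121L) {
  threshold <- match.arg(threshold)
  if (threshold == "fixed" && (is.null(threshold_value) ||
                               !is.numeric(threshold_value)))
    stop("`threshold_value` is required for threshold = \"fixed\"", call. = FALSE)
  if (!connectivity %in% c(6L, 26L))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  stopifnot(background_radius > 0, smoothing_width > 0, min_voxels >= 1)
  structure(list(background_radius = background_radius,
                 smoothing_width = smoothing_width,
                 threshold = threshold, threshold_value = threshold_value,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels)),
            class = "segmentation_params")
}

# integer offsets (dz, dy, dx) whose physical displacement lies within a
# ball of the given radius, clamped to the grid extent per axis
ball_offsets <- function(radius, spacing, dims) {
  nmax <- pmin(floor(radius / spacing), dims - 1L)
  dz <- -nmax[1]:nmax[1]; dy <- -nmax[2]:nmax[2]; dx <- -nmax[3]:nmax[3]
  g <- expand.grid(dz = dz, dy = dy, dx = dx)
  d2 <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' volume with a ball structuring element of the given physical radius
#' (erosion then dilation), and subtracts it, clipping at zero. A constant
#' offset is removed exactly; compact bright objects smaller than the ball
#' survive with the local background removed.
#'
#' @param grid a [voxel_grid].
#' @param radius ball radius in um (> 0); the default reproduces the
#'   published 37.1 um setting.
#' @return a [voxel_grid] of the background-subtracted volume. If the
#'   radius is smaller than one voxel in any axis the input is returned
#'   unchanged with a warning.
#' @export
subtract_background <- function(grid, radius = 37.1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be > 0", call. = FALSE)
  if (radius < max(grid$spacing)) {
    warning("background radius ", radius,
            " um is below one voxel in at least one axis; returning input unchanged")
    return(grid)
  }
  dims <- dim(grid$values)
  extent2 <- sum(((dims - 1L) * grid$spacing)^2)
  if (radius^2 >= extent2) {
    # the ball covers the whole grid from every voxel: opening is the
    # global minimum everywhere
    bg <- min(grid$values)
    out <- pmax(grid$values - bg, 0)
    return(voxel_grid(array(out, dims), grid$spacing))
  }
  off <- ball_offsets(radius, grid$spacing, dims)
  if (as.double(nrow(off)) * prod(dims) > 5e9)
    stop("background radius too large for this grid (structuring element of ",
         nrow(off), " voxels); downsample or reduce the radius", call. = FALSE)
  er <- cpp_gray_morph(as.numeric(grid$values), dims, off, FALSE)
  op <- cpp_gray_morph(er, dims, off, TRUE)
  out <- pmax(as.numeric(grid$values) - op, 0)
  voxel_grid(array(out, dims), grid$spacing)
}

gaussian_kernel_1d <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian filter with per-axis sigma (in voxels) equal to
#' `width / spacing_axis`, so anisotropic grids are smoothed isotropically
#' in physical space. The kernel is normalized and the boundary mirrored,
#' so a constant field is preserved exactly and total intensity of interior
#' features is conserved. `width` is the Gaussian sigma in um; at the
#' published width 0.129 um and isotropic 0.0645 um spacing this is
#' sigma = 2 voxels per axis.
#'
#' @param grid a [voxel_grid].
#' @param width Gaussian sigma in um (> 0).
#' @return a smoothed [voxel_grid].
#' @export
smooth_gaussian <- function(grid, width = 0.129) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(width) || width <= 0)
    stop("`width` must be > 0", call. = FALSE)
  dims <- dim(grid$values)
  v <- as.numeric(grid$values)
  for (axis in 1:3) {
    sigma <- width / grid$spacing[axis]
    if (dims[axis] == 1L) next
    v <- cpp_convolve_axis(v, dims, gaussian_kernel_1d(sigma), axis - 1L)
  }
  voxel_grid(array(v, dims), grid$spacing)
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin linear histogram.
#' Exposed because the segmentation default depends on it; returns the bin
#' upper edge so that `values > threshold` is the foreground.
#'
#' @param values numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  w <- cumsum(as.numeric(h))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1L]
}

#' Threshold and label a preprocessed volume
#'
#' Binarizes the grid (Otsu by default, or a fixed cutoff), labels connected
#' components at the configured connectivity, and relabels them
#' consecutively by descending voxel count. An all-background result is a
#' valid empty [label_volume], not an error.
#'
#' @param grid a preprocessed [voxel_grid].
#' @param params a [segmentation_params()].
#' @return a [label_volume].
#' @export
segment_volume <- function(grid, params = segmentation_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "segmentation_params"))
  thr <- if (params$threshold == "otsu") otsu_threshold(grid$values)
         else params$threshold_value
  mask <- grid$values > thr
  if (!any(mask))
    return(label_volume(array(0L, dim(grid$values)), grid$spacing))
  dims <- dim(grid$values)
  lab <- cpp_label_components(as.logical(mask), dims, params$connectivity)
  relabel_by_size(label_volume(array(lab, dims), grid$spacing))
}

#' Remove objects below a voxel-count cutoff
#'
#' "Smaller than" is strict: an object with exactly `min_voxels` voxels is
#' retained (the published 121-voxel exclusion keeps 121-voxel objects).
#' Survivors are relabeled consecutively preserving descending-size order.
#' Idempotent, and never increases the object count.
#'
#' @param labels a [label_volume].
#' @param min_voxels positive integer cutoff (default 121).
#' @return a filtered [label_volume].
#' @export
filter_small <- function(labels, min_voxels = 121L) {
  stopifnot(inherits(labels, "label_volume"))
  if (!is.numeric(min_voxels) || min_voxels < 1)
    stop("`min_voxels` must be >= 1", call. = FALSE)
  sz <- object_sizes(labels)
  drop <- as.integer(names(sz))[sz < min_voxels]
  new <- labels$labels
  if (length(drop)) new[new %in% drop] <- 0L
  relabel_by_size(label_volume(new, labels$spacing))
}

#' Full preprocessing and segmentation pipeline
#'
#' Fixed stage order: background subtraction, Gaussian smoothing,
#' threshold + connected-component labeling, size filtering. Each stage
#' logs its output object count via `message()`.
#'
#' @param grid raw [voxel_grid].
#' @param params a [segmentation_params()].
#' @param verbose emit per-stage messages (default TRUE).
#' @return a [label_volume].
#' @export
preprocess_and_segment <- function(grid, params = segmentation_params(),
                                   verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  g <- subtract_background(grid, params$background_radius)
  say("background subtracted (radius ", params$background_radius, " um)")
  g <- smooth_gaussian(g, params$smoothing_width)
  say("smoothed (sigma ", params$smoothing_width, " um)")
  lab <- segment_volume(g, params)
  say("segmented: ", n_objects(lab), " object(s) [", params$threshold,
      " threshold, connectivity ", params$connectivity, "]")
  out <- filter_small(lab, params$min_voxels)
  say("size filter (>= ", params$min_voxels, " voxels): ",
      n_objects(out), " object(s) retained")
  out
}
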
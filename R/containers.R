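#' Voxel grid: a 3D intensity volume with physical spacing
#'
#' The basic container for volumetric image data. Axis order is (z, y, x)
#' throughout the package: `values[z, y, x]`, `spacing = c(z, y, x)` in
#' micrometers per voxel. The physical center of voxel `(i, j, k)` (1-based)
#' is at `(i - 0.5, j - 0.5, k - 0.5) * spacing`.
#'
#' @param values numeric 3D array of intensities (arbitrary units).
#' @param spacing numeric length-3, micrometers per voxel along (z, y, x);
#'   all components must be strictly positive.
#' @return An object of class `voxel_grid`: a list with elements `values`
#'   and `spacing`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 5, 6)), spacing = c(0.09, 0.065, 0.065))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (z, y, x)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(list(values = values, spacing = spacing), class = "voxel_grid")
}

#' Label volume: segmented objects on a voxel grid
#'
#' Integer-labeled volume sharing the geometry conventions of
#' [voxel_grid()]: 0 is background, positive integers identify objects.
#' After any relabeling step in this package, labels are consecutive
#' `1..K` in descending voxel-count order.
#'
#' @param labels integer 3D array, non-negative.
#' @param spacing numeric length-3, micrometers per voxel along (z, y, x).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("`labels` must be non-negative integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (z, y, x)", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' Physical volume of one voxel in cubic micrometers
#' @param x a `voxel_grid` or `label_volume`.
#' @return scalar, product of the per-axis spacings (um^3).
#' @export
voxel_size <- function(x) prod(x$spacing)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  k <- n_objects(x)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), spacing %s um, %d object%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              k, if (k == 1) "" else "s"))
  invisible(x)
}

#' Number of distinct objects in a label volume
#' @param labels a `label_volume`.
#' @return integer count of distinct nonzero labels.
#' @export
n_objects <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  length(setdiff(unique(as.vector(labels$labels)), 0L))
}

#' Per-object voxel counts
#' @param labels a `label_volume`.
#' @return named integer vector, names are label ids, descending label order
#'   not guaranteed; use [relabel_by_size()] for canonical ordering.
#' @export
object_sizes <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  v <- labels$labels[labels$labels > 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- table(v)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Relabel objects consecutively by descending voxel count
#'
#' Ties are broken by the original label id so the result is deterministic.
#'
#' @param labels a `label_volume`.
#' @return a `label_volume` with labels `1..K`, object 1 the largest.
#' @export
relabel_by_size <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  sz <- object_sizes(labels)
  if (length(sz) == 0L) return(labels)
  ids <- as.integer(names(sz))
  ord <- order(-sz, ids)
  map <- integer(max(ids))
  map[ids[ord]] <- seq_along(ord)
  new <- labels$labels
  pos <- new > 0L
  new[pos] <- map[new[pos]]
  label_volume(new, labels$spacing)
}

#' 2D cell scene: mask, mitochondrial signal and geometry
#'
#' Container for the 2D fluorescence-style analysis: a binary cell mask, a
#' non-negative intensity image of the same shape (mitochondrial signal),
#' the pixel spacing, and the mask centroid (row, col, 1-based pixel
#' coordinates). Intensity outside the mask is ignored by all zone
#' operations.
#'
#' @param mask logical (or 0/1) matrix, the cell footprint.
#' @param intensity numeric matrix, same shape, >= 0.
#' @param spacing scalar, micrometers per pixel (isotropic).
#' @param centroid optional numeric length-2 (row, col); derived from the
#'   mask when missing.
#' @return An object of class `cell_scene`.
#' @export
cell_scene <- function(mask, intensity, spacing, centroid = NULL) {
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!is.matrix(intensity) || !all(dim(intensity) == dim(mask)))
    stop("`intensity` must be a matrix matching `mask`", call. = FALSE)
  if (any(intensity < 0)) stop("`intensity` must be non-negative", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a positive scalar (um/pixel)", call. = FALSE)
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  if (is.null(centroid)) {
    w <- which(mask, arr.ind = TRUE)
    centroid <- c(mean(w[, 1]), mean(w[, 2]))
  }
  structure(list(mask = mask, intensity = intensity, spacing = spacing,
                 centroid = as.numeric(centroid)), class = "cell_scene")
}
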
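#' Label connected components in a 2D mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default; diagonal contacts join) or 4.
#' @return integer matrix of labels, 0 background, relabeled by descending
#'   pixel count.
#' @export
label2d <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  m <- matrix(as.logical(mask), nrow = nrow(mask))
  dims <- c(1L, nrow(m), ncol(m))
  lab <- cpp_label_components(as.logical(m), dims,
                              if (connectivity == 8L) 26L else 6L)
  lv <- relabel_by_size(label_volume(array(lab, dims), c(1, 1, 1)))
  matrix(lv$labels[1L, , ], nrow = nrow(m))
}

# marching-squares iso-contours of a matrix at `level` with linear
# interpolation, returned as closed loops (matrices of (row, col) vertices).
# The image is zero-padded so every loop closes. Ambiguous saddle cells are
# resolved by the cell-center mean.
ms_contours <- function(img, level = 0.5) {
  p <- matrix(0, nrow(img) + 2L, ncol(img) + 2L)
  p[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  nr <- nrow(p); nc <- ncol(p)
  segs <- list()
  interp <- function(a, b) (level - a) / (b - a)
  for (r in 1:(nr - 1L)) for (cc in 1:(nc - 1L)) {
    v00 <- p[r, cc]; v01 <- p[r, cc + 1L]
    v10 <- p[r + 1L, cc]; v11 <- p[r + 1L, cc + 1L]
    b <- c(v00 >= level, v01 >= level, v11 >= level, v10 >= level)
    if (all(b) || !any(b)) next
    pts <- list()
    if (b[1] != b[2]) pts$top    <- c(r, cc + interp(v00, v01))
    if (b[2] != b[3]) pts$right  <- c(r + interp(v01, v11), cc + 1)
    if (b[4] != b[3]) pts$bottom <- c(r + 1, cc + interp(v10, v11))
    if (b[1] != b[4]) pts$left   <- c(r + interp(v00, v10), cc)
    nm <- names(pts)
    if (length(pts) == 2L) {
      segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
    } else {
      # saddle: pair crossings by the center average
      ctr_in <- mean(c(v00, v01, v10, v11)) >= level
      # corners TL,TR set iff b[1],b[2]; saddle has b = (T,F,T,F) or (F,T,F,T)
      if (xor(b[1], ctr_in)) {
        segs[[length(segs) + 1L]] <- rbind(pts$top, pts$left)
        segs[[length(segs) + 1L]] <- rbind(pts$bottom, pts$right)
      } else {
        segs[[length(segs) + 1L]] <- rbind(pts$top, pts$right)
        segs[[length(segs) + 1L]] <- rbind(pts$bottom, pts$left)
      }
    }
  }
  if (length(segs) == 0L) return(list())
  key <- function(pt) sprintf("%.6f_%.6f", pt[1], pt[2])
  ends <- matrix("", length(segs), 2L)
  for (i in seq_along(segs)) ends[i, ] <- c(key(segs[[i]][1, ]), key(segs[[i]][2, ]))
  inc <- split(rep(seq_along(segs), 2L), c(ends[, 1], ends[, 2]))
  used <- logical(length(segs))
  loops <- list()
  for (s0 in seq_along(segs)) {
    if (used[s0]) next
    used[s0] <- TRUE
    loop <- list(segs[[s0]][1, ], segs[[s0]][2, ])
    cur_key <- ends[s0, 2]; start_key <- ends[s0, 1]
    repeat {
      if (cur_key == start_key) break
      cand <- inc[[cur_key]]
      nxt <- cand[!used[cand]]
      if (length(nxt) == 0L) break  # should not happen on closed fields
      i <- nxt[1L]; used[i] <- TRUE
      if (ends[i, 1] == cur_key) {
        loop[[length(loop) + 1L]] <- segs[[i]][2, ]; cur_key <- ends[i, 2]
      } else {
        loop[[length(loop) + 1L]] <- segs[[i]][1, ]; cur_key <- ends[i, 1]
      }
    }
    m <- do.call(rbind, loop)
    m <- m[-nrow(m), , drop = FALSE]               # drop repeated closing vertex
    m[, 1] <- m[, 1] - 1; m[, 2] <- m[, 2] - 1     # undo padding offset
    loops[[length(loops) + 1L]] <- m
  }
  loops
}

poly_length <- function(v) {
  d <- v - v[c(2:nrow(v), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

poly_area <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  xn <- x[c(2:length(x), 1L)]; yn <- y[c(2:length(y), 1L)]
  abs(sum(x * yn - xn * y)) / 2
}

#' Sub-pixel perimeter of 2D objects
#'
#' Traces marching-squares iso-contours at level 0.5 with linear
#' interpolation, per 8-connected object. The perimeter is the length of
#' the object's outer contour (the loop of largest enclosed area) times
#' the pixel spacing; interior hole contours are reported separately and do
#' not count toward `P`. Sub-pixel contours are used instead of crack-edge
#' counting, which overestimates smooth perimeters by ~27%; the
#' marching-squares polygon itself still carries a known upward bias of
#' about 6-9% on digitized smooth convex boundaries (it is exact for
#' axis-aligned and diagonal straight edges), identical to other
#' marching-squares implementations. Comparisons between conditions
#' measured at the same resolution are unaffected.
#'
#' @param mask binary matrix (or labeled integer matrix, labels kept as
#'   object ids).
#' @param spacing um per pixel (isotropic).
#' @return list with `contours` (per object: list of loops, (row, col)
#'   vertex matrices in um) and `metrics` (data.frame: id, perimeter_um,
#'   n_holes, hole_perimeter_um). Empty mask yields empty results.
#' @export
trace_perimeter <- function(mask, spacing = 1) {
  stopifnot(is.matrix(mask), is.numeric(spacing), spacing > 0)
  labels <- if (all(mask %in% c(0, 1)) || is.logical(mask))
    label2d(mask) else mask
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  metrics <- data.frame(id = numeric(0), perimeter_um = numeric(0),
                        n_holes = integer(0), hole_perimeter_um = numeric(0))
  contours <- list()
  for (id in ids) {
    loops <- ms_contours((labels == id) * 1)
    areas <- vapply(loops, poly_area, 1.0)
    outer_i <- which.max(areas)
    P <- poly_length(loops[[outer_i]]) * spacing
    holes <- setdiff(seq_along(loops), outer_i)
    hp <- if (length(holes))
      sum(vapply(loops[holes], poly_length, 1.0)) * spacing else 0
    metrics <- rbind(metrics, data.frame(
      id = id, perimeter_um = P, n_holes = length(holes),
      hole_perimeter_um = hp))
    contours[[as.character(id)]] <-
      lapply(loops[c(outer_i, holes)], function(v) v * spacing)
  }
  list(contours = contours, metrics = metrics)
}

# centers of pixels on the object's 4-boundary (pixels with a 4-neighbor
# outside the object or on the image border)
boundary_pixel_centers <- function(labels, id) {
  m <- labels == id
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(m & !core, arr.ind = TRUE)
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  hull <- if (nrow(pts) > 3L) pts[grDevices::chull(pts[, 2], pts[, 1]), ,
                                  drop = FALSE] else pts
  max(stats::dist(hull))
}

#' Length (max Feret diameter) and cross-sectional area of a 2D object
#'
#' Length is the maximum Feret diameter: the largest pairwise distance
#' between boundary-pixel centers (so a 1 x 50 px object at 0.1 um/px has
#' length 4.9 um, 49 inter-center units). Area is the exact pixel count
#' times the squared spacing.
#'
#' @param labels2d integer label matrix (0 = background).
#' @param spacing um per pixel.
#' @param id object label present in `labels2d`.
#' @return list with `length` (um) and `area` (um^2).
#' @export
length_and_area <- function(labels2d, spacing, id) {
  stopifnot(is.matrix(labels2d), spacing > 0)
  n <- sum(labels2d == id)
  if (n == 0L) stop("object id ", id, " not present", call. = FALSE)
  bp <- boundary_pixel_centers(labels2d, id)
  list(length = max_pairwise_dist(bp) * spacing, area = n * spacing^2)
}

#' Object count and total area of a labeled 2D image
#'
#' @param labels2d integer label matrix.
#' @param spacing um per pixel.
#' @return list with `count` and `total_area` (um^2, the exact sum of
#'   per-object areas). An empty image gives (0, 0).
#' @export
count_and_total_area <- function(labels2d, spacing = 1) {
  stopifnot(is.matrix(labels2d), spacing > 0)
  ids <- setdiff(unique(as.vector(labels2d)), 0)
  list(count = length(ids),
       total_area = sum(labels2d != 0) * spacing^2)
}

#' Cristae area and density within a mitochondrial cross-section
#'
#' Per-crista areas from a labeled cristae image, and cristae density =
#' total cristae area / mitochondrion area (dimensionless, in [0, 1]).
#' Every crista pixel must lie inside the mitochondrial mask. When a
#' section thickness is supplied, per-crista volumes (area x thickness)
#' are also reported; a 2D section carries no intrinsic volume otherwise.
#'
#' @param mito_mask binary matrix, the mitochondrion cross-section.
#' @param cristae_labels integer matrix of the same shape, one label per
#'   crista (0 = background).
#' @param spacing um per pixel.
#' @param section_thickness optional section thickness in um.
#' @return list with `areas` (named per-crista, um^2), `density`, `n`, and
#'   optionally `volumes` (um^3).
#' @export
crista_metrics <- function(mito_mask, cristae_labels, spacing = 1,
                           section_thickness = NULL) {
  stopifnot(is.matrix(mito_mask), is.matrix(cristae_labels),
            all(dim(mito_mask) == dim(cristae_labels)), spacing > 0)
  mito <- matrix(as.logical(mito_mask), nrow = nrow(mito_mask))
  if (any(cristae_labels != 0 & !mito))
    stop("cristae pixels found outside the mitochondrial mask", call. = FALSE)
  ids <- sort(setdiff(unique(as.vector(cristae_labels)), 0))
  areas <- vapply(ids, function(id) sum(cristae_labels == id) * spacing^2, 1.0)
  names(areas) <- ids
  mito_area <- sum(mito) * spacing^2
  out <- list(areas = areas, n = length(ids),
              density = if (mito_area > 0) sum(areas) / mito_area else 0)
  if (!is.null(section_thickness)) {
    stopifnot(section_thickness > 0)
    out$volumes <- areas * section_thickness
  }
  out
}

#' Full 2D section metrics table
#'
#' Convenience wrapper combining [trace_perimeter()] and
#' [length_and_area()] into the CSV schema used by the command line:
#' one row per object with perimeter, Feret length and area.
#'
#' @param labels2d integer label matrix (or binary mask, labeled at
#'   8-connectivity).
#' @param spacing um per pixel.
#' @return data.frame: id, perimeter_um, length_um, area_um2.
#' @export
measure_sections <- function(labels2d, spacing = 1) {
  if (is.logical(labels2d) || all(labels2d %in% c(0, 1)))
    labels2d <- label2d(labels2d)
  tp <- trace_perimeter(labels2d, spacing)
  if (nrow(tp$metrics) == 0L)
    return(data.frame(id = numeric(0), perimeter_um = numeric(0),
                      length_um = numeric(0), area_um2 = numeric(0)))
  la <- lapply(tp$metrics$id, function(id) length_and_area(labels2d, spacing, id))
  data.frame(id = tp$metrics$id,
             perimeter_um = tp$metrics$perimeter_um,
             length_um = vapply(la, `[[`, 1.0, "length"),
             area_um2 = vapply(la, `[[`, 1.0, "area"))
}
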
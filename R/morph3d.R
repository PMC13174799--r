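#' Voxel-based object volume
#'
#' `V = N_vox * (x * y * z)`: the number of voxels assigned to the object
#' times the calibrated voxel volume. Exact by definition; the mesh-based
#' volume of [mesh_measures()] is the complementary estimator.
#'
#' @param labels a [label_volume].
#' @param id positive object label present in `labels`.
#' @return volume in um^3.
#' @export
voxel_volume <- function(labels, id) {
  stopifnot(inherits(labels, "label_volume"))
  n <- sum(labels$labels == id)
  if (n == 0L) stop("object id ", id, " not present in the label volume",
                    call. = FALSE)
  n * voxel_size(labels)
}

#' Extract a closed surface mesh for one labeled object
#'
#' Iso-surfaces the object's binary mask at level 0.5 using naive surface
#' nets (dual contouring: one vertex per boundary cell at the centroid of
#' its edge crossings, two triangles per sign-changing grid edge). The mask
#' is zero-padded by one voxel so the surface is always closed, vertex
#' coordinates are scaled into physical um, and the global orientation is
#' fixed so the enclosed volume is positive. A single voxel yields a small
#' closed octahedron-like surface.
#'
#' Surface nets is used instead of classic marching cubes because, on
#' binary masks, marching-cubes triangle soup overestimates sphere surface
#' area by 7-9% while the dual mesh stays within ~2-3%; the mesh is
#' watertight by construction. No smoothing or decimation is applied, so
#' the estimator is deterministic.
#'
#' @param labels a [label_volume].
#' @param id positive object label present in `labels`.
#' @return a `surface_mesh`: list with `vertices` (n x 3 matrix, um,
#'   columns z, y, x) and `faces` (m x 3 integer matrix, 1-based,
#'   consistently wound).
#' @export
extract_mesh <- function(labels, id) {
  stopifnot(inherits(labels, "label_volume"))
  pos <- which(labels$labels == id, arr.ind = TRUE)
  if (nrow(pos) == 0L)
    stop("object id ", id, " not present in the label volume", call. = FALSE)
  # crop to the object's bounding box plus one voxel of zero padding
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  d <- hi - lo + 3L
  sub <- array(0, dim = d)
  sub[cbind(pos[, 1] - lo[1] + 2L, pos[, 2] - lo[2] + 2L, pos[, 3] - lo[3] + 2L)] <- 1
  mesh <- cpp_surface_nets(as.numeric(sub), dim(sub), 0.5)
  v <- mesh$vertices
  # sample index i (0-based, padded frame) -> original 1-based index
  # (i - 1 + lo), voxel center at (index - 0.5) * spacing
  for (a in 1:3)
    v[, a] <- (v[, a] - 1 + lo[a] - 0.5) * labels$spacing[a]
  m <- structure(list(vertices = v, faces = mesh$faces), class = "surface_mesh")
  if (signed_mesh_volume(m) < 0)
    m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

# signed volume via the divergence theorem, tetrahedra against the vertex
# centroid (mathematically origin-independent for closed meshes; the
# centroid reference reduces floating-point cancellation)
signed_mesh_volume <- function(mesh) {
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c <- v[mesh$faces[, 3], , drop = FALSE]
  cx <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(a * cx) / 6
}

mesh_edge_check <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bad_count <- names(cnt)[cnt != 2L]
  # opposite winding: each directed edge must appear exactly once
  dkey <- paste(he[, 1], he[, 2])
  dup <- unique(dkey[duplicated(dkey)])
  unique(c(bad_count, dup))
}

#' Surface area and enclosed volume of a closed mesh
#'
#' `SA` is the sum of triangle areas; `V` is the absolute total signed
#' volume of the tetrahedra spanned by each face (divergence theorem). The
#' mesh must be closed and consistently oriented: every undirected edge
#' shared by exactly two faces with opposite winding, otherwise an
#' integrity error reports the offending edges.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `SA` (um^2) and `V` (um^3).
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  bad <- mesh_edge_check(mesh)
  if (length(bad))
    stop("mesh is not closed/consistently oriented; offending edges: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sa <- sum(sqrt(rowSums(cx^2))) / 2
  list(SA = sa, V = abs(signed_mesh_volume(mesh)))
}

#' Sphericity and the Mitochondrial Complexity Index
#'
#' From a volume `V` (um^3) and surface area `SA` (um^2):
#' \deqn{\Phi = \pi^{1/3} (6V)^{2/3} / SA}
#' \deqn{MCI_{root} = SA^{3/2} / (4 \pi V)}
#' \deqn{MCI_{sq} = SA^3 / (16 \pi^2 V^2)}
#' A perfect sphere has sphericity 1 and `MCI_sq = 9/(4*pi)`, the minimum
#' attainable by the isoperimetric inequality; elongation and branching
#' lower sphericity and raise MCI without bound. Both MCI forms encode the
#' same information (`MCI_sq = MCI_root^2`); the squared form expands the
#' dynamic range. The identity `MCI_sq * Phi^3 = 9/(4*pi)` holds exactly
#' for any (V, SA).
#'
#' @param V volume in um^3 (> 0).
#' @param SA surface area in um^2 (> 0).
#' @return list with `sphericity`, `mci_root`, `mci_sq`.
#' @examples
#' r <- 5
#' shape_indices(4 / 3 * pi * r^3, 4 * pi * r^2)$sphericity  # 1
#' @export
shape_indices <- function(V, SA) {
  if (!is.numeric(V) || !is.numeric(SA) || any(V <= 0) || any(SA <= 0))
    stop("`V` and `SA` must be positive", call. = FALSE)
  list(sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / SA,
       mci_root = SA^(3 / 2) / (4 * pi * V),
       mci_sq = SA^3 / (16 * pi^2 * V^2))
}

#' Per-object morphometrics table
#'
#' Measures every labeled object: voxel count, voxel- and mesh-based
#' volume, mesh surface area, sphericity and both MCI forms. Shape indices
#' use the mesh volume by default (`volume_source = "voxel"` switches to
#' the voxel count convention); both volumes are always reported.
#'
#' @param labels a [label_volume]; an empty volume yields an empty table.
#' @param volume_source `"mesh"` (default) or `"voxel"`: which volume
#'   enters the shape indices.
#' @param complexity_per_volume also report `mci_sq / v_mesh_um3` as column
#'   `mci_per_um3` (a convenience ratio; not a published quantity).
#' @return data.frame with columns `id`, `n_vox`, `v_voxel_um3`,
#'   `v_mesh_um3`, `sa_um2`, `sphericity`, `mci_root`, `mci_sq`, sorted by
#'   id.
#' @export
measure_objects <- function(labels, volume_source = c("mesh", "voxel"),
                            complexity_per_volume = FALSE) {
  stopifnot(inherits(labels, "label_volume"))
  volume_source <- match.arg(volume_source)
  ids <- sort(setdiff(unique(as.vector(labels$labels)), 0L))
  empty <- data.frame(id = integer(0), n_vox = integer(0),
                      v_voxel_um3 = numeric(0), v_mesh_um3 = numeric(0),
                      sa_um2 = numeric(0), sphericity = numeric(0),
                      mci_root = numeric(0), mci_sq = numeric(0))
  if (length(ids) == 0L) return(empty)
  vox <- voxel_size(labels)
  rows <- lapply(ids, function(id) {
    n <- sum(labels$labels == id)
    mm <- mesh_measures(extract_mesh(labels, id))
    V <- if (volume_source == "mesh") mm$V else n * vox
    si <- shape_indices(V, mm$SA)
    data.frame(id = id, n_vox = n, v_voxel_um3 = n * vox, v_mesh_um3 = mm$V,
               sa_um2 = mm$SA, sphericity = si$sphericity,
               mci_root = si$mci_root, mci_sq = si$mci_sq)
  })
  out <- do.call(rbind, rows)
  if (complexity_per_volume) out$mci_per_um3 <- out$mci_sq / out$v_mesh_um3
  rownames(out) <- NULL
  out
}
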
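# Programmatic fixtures shared across test files. Everything is generated
# in code; no stored image data.

# digitized ball: label volume with one sphere of radius r_vox voxels at
# unit-ish spacing
digitized_ball <- function(r_vox, spacing = c(1, 1, 1), pad = 3) {
  ctr <- (r_vox + pad) * spacing
  shape <- rep(2 * (r_vox + pad), 3)
  rasterize(list(sphere_spec(ctr, r_vox * spacing[1])),
            spacing = spacing, shape = shape)
}

# binary disc mask of pixel radius r in an n x n image
disc_mask <- function(r, n = 2L * r + 9L) {
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- t(row)
  (row - ctr)^2 + (col - ctr)^2 <= r^2
}

# hand-built closed unit cube mesh (12 triangles, consistent winding)
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),       # bottom
             c(5, 6, 7), c(5, 7, 8),       # top
             c(1, 2, 6), c(1, 6, 5),       # front
             c(2, 3, 7), c(2, 7, 6),       # right
             c(3, 4, 8), c(3, 8, 7),       # back
             c(4, 1, 5), c(4, 5, 8))       # left
  structure(list(vertices = v, faces = f), class = "surface_mesh")
}

# brute-force max pairwise distance (independent Feret oracle)
brute_feret <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1L))
    for (j in (i + 1L):nrow(pts))
      best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  best
}
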
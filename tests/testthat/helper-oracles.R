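# Independent oracles, deliberately implemented apart from the package:
# a pure-R ray caster, the 2-D shoelace area, and small fixture builders.

# shoelace area of a closed 2-D polygon (vertices in order, not repeated)
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# does the segment O -> Tgt cross triangle j of (V, F)? Pure-R Moller-Trumbore
# with the same strict-interior convention as the compiled path, but written
# independently (barycentric solve via explicit determinants).
r_segment_blocked <- function(V, F, O, Tgt, exclude = integer(0)) {
  D <- Tgt - O
  for (j in seq_len(nrow(F))) {
    if (j %in% exclude) next
    v0 <- V[F[j, 1L], ]; v1 <- V[F[j, 2L], ]; v2 <- V[F[j, 3L], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    pv <- c(D[2] * e2[3] - D[3] * e2[2],
            D[3] * e2[1] - D[1] * e2[3],
            D[1] * e2[2] - D[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- O - v0
    u <- sum(tv * pv) / det
    if (u < 1e-9 || u > 1 - 1e-9) next
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(D * qv) / det
    if (v < 1e-9 || u + v > 1 - 1e-9) next
    t <- sum(e2 * qv) / det
    if (t > 1e-6 && t < 1 - 1e-6) return(TRUE)
  }
  FALSE
}

# per-pose visibility of selected faces by the R oracle: plant rotates by
# 'angles' (deg); camera fixed at cam_pos; same incidence rule as the rig
r_visibility <- function(scene, cam_pos, angles, faces_idx,
                         max_incidence = 70) {
  cos_min <- cos(max_incidence * pi / 180)
  out <- matrix(FALSE, length(faces_idx), length(angles))
  for (a in seq_along(angles)) {
    ang <- angles[a] * pi / 180
    R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    V <- scene$vertices %*% t(R)
    F <- scene$faces
    for (k in seq_along(faces_idx)) {
      i <- faces_idx[k]
      tri <- V[F[i, ], , drop = FALSE]
      O <- colMeans(tri)
      n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
               (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
             (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
               (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
             (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
      n <- n / sqrt(sum(n^2))
      D <- cam_pos - O
      cosang <- abs(sum(n * D)) / sqrt(sum(D^2))
      if (cosang < cos_min) next
      out[k, a] <- !r_segment_blocked(V, F, O, cam_pos, exclude = i)
    }
  }
  out
}

# triangulated unit hemisphere (pole at +Z, equator at z = 0)
make_hemisphere <- function(n_phi = 90L, n_theta = 180L) {
  phi <- seq(0, pi / 2, length.out = n_phi + 1L)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  verts <- rbind(c(0, 0, 1))
  for (i in 2:(n_phi + 1L)) {
    verts <- rbind(verts, cbind(sin(phi[i]) * cos(theta),
                                sin(phi[i]) * sin(theta),
                                cos(phi[i])))
  }
  idx <- function(ring, j) 1L + (ring - 1L) * n_theta + (j - 1L) %% n_theta + 1L
  j <- seq_len(n_theta)
  faces <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  for (r in seq_len(n_phi - 1L)) {
    faces <- rbind(faces,
                   cbind(idx(r, j), idx(r + 1L, j), idx(r + 1L, j + 1L)),
                   cbind(idx(r, j), idx(r + 1L, j + 1L), idx(r, j + 1L)))
  }
  triangle_mesh(verts, faces)
}

# open vertical cylinder (occluder fixture)
make_cylinder_mesh <- function(radius, z0, z1, sides = 24L) {
  theta <- 2 * pi * (seq_len(sides) - 1L) / sides
  verts <- rbind(cbind(radius * cos(theta), radius * sin(theta), z0),
                 cbind(radius * cos(theta), radius * sin(theta), z1))
  j <- seq_len(sides)
  nxt <- j %% sides + 1L
  faces <- rbind(cbind(j, sides + j, sides + nxt),
                 cbind(j, sides + nxt, nxt))
  triangle_mesh(verts, faces)
}

# small single-leaf turntable scene shared by several tests
make_leaf_scene <- function(length = 50, width = 34, inclination = 0,
                            height = 30, resolution = 2.5) {
  leaf <- generate_leaf(length, width, inclination = inclination,
                        attach = c(-length / 2, 0, height),
                        resolution = resolution, label = "L1")
  soil <- triangle_mesh(cbind(c(-135, 135, 135, -135),
                              c(-135, -135, 135, 135), 0),
                        rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                        labels = rep("soil", 2L))
  list(scene = phenomesh:::merge_meshes(list(leaf$mesh, soil)),
       leaf = leaf,
       rig = camera_rig(center = c(0, 0, height)))
}
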
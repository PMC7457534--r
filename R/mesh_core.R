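#' Construct a triangle mesh
#'
#' The common currency of the package: a triangle mesh with vertex coordinates
#' in millimetres, Z pointing to the zenith and the soil plane at z = 0.
#' Faces may carry an organ label (e.g. \code{"L1"}, \code{"stem1"},
#' \code{"soil"}) used by the trait-extraction and segmentation stages.
#'
#' Degenerate (zero-area) faces are dropped at construction; the number of
#' dropped faces is reported via a message.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm (columns x, y, z).
#' @param faces integer matrix, m x 3, one-based vertex indices.
#' @param labels optional character vector of per-face organ labels (length m).
#' @param clean drop degenerate faces (default \code{TRUE}).
#' @return an object of class \code{triangle_mesh} with components
#'   \code{vertices}, \code{faces} and \code{labels}.
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(faces))
      stop("'labels' must have one entry per face")
  }
  mesh <- structure(list(vertices = vertices, faces = faces, labels = labels),
                    class = "triangle_mesh")
  if (clean && nrow(faces) > 0L) {
    a <- face_areas(mesh)
    bad <- a <= 1e-10
    if (any(bad)) {
      message(sum(bad), " degenerate face(s) dropped")
      mesh$faces <- mesh$faces[!bad, , drop = FALSE]
      if (!is.null(mesh$labels)) mesh$labels <- mesh$labels[!bad]
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  }
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of faces / vertices
#' @param mesh a \code{triangle_mesh}.
#' @return integer count.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname n_faces
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# edge vectors of each face: list of two m x 3 matrices
.face_edges <- function(vertices, faces) {
  v0 <- vertices[faces[, 1L], , drop = FALSE]
  list(e1 = vertices[faces[, 2L], , drop = FALSE] - v0,
       e2 = vertices[faces[, 3L], , drop = FALSE] - v0)
}

.cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Per-face areas
#'
#' Area of each triangle as half the magnitude of the cross product of two
#' edge vectors, in square millimetres.
#'
#' @param mesh a \code{triangle_mesh} (or any list with \code{vertices} and
#'   \code{faces}).
#' @return numeric vector of areas (mm^2), one per face.
#' @export
face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(numeric(0))
  e <- .face_edges(mesh$vertices, mesh$faces)
  n <- .cross3(e$e1, e$e2)
  0.5 * sqrt(rowSums(n * n))
}

#' Per-face normals
#'
#' @param mesh a \code{triangle_mesh}.
#' @param unit normalise to unit length (default \code{TRUE}).
#' @return m x 3 matrix of face normals.
#' @export
face_normals <- function(mesh, unit = TRUE) {
  e <- .face_edges(mesh$vertices, mesh$faces)
  n <- .cross3(e$e1, e$e2)
  if (unit) {
    len <- sqrt(rowSums(n * n))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Per-face inclination angles
#'
#' The mesh inclination angle of a face is the zenith angle of its normal
#' vector, folded into [0, 90] degrees so that the result does not depend on
#' which side of the surface the normal points to: a horizontal face scores
#' 0 degrees, a vertical face 90 degrees.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return numeric vector of angles in degrees, one per face, in [0, 90].
#' @export
face_inclinations <- function(mesh) {
  n <- face_normals(mesh, unit = TRUE)
  cosz <- pmin(1, abs(n[, 3L]))
  acos(cosz) * 180 / pi
}

#' Face centroids
#' @param mesh a \code{triangle_mesh}.
#' @return m x 3 matrix of centroids (mm).
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1L], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2L], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3L], , drop = FALSE]) / 3
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a \code{triangle_mesh}.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1, checked to
#'   1e-8).
#' @param translation length-3 numeric translation (mm).
#' @return the transformed \code{triangle_mesh}.
#' @export
rigid_transform <- function(mesh, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("'rotation' must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("'rotation' is not orthonormal")
  if (det(rotation) < 0)
    stop("'rotation' must be a proper rotation (det +1), not a reflection")
  out <- mesh
  out$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  out
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param angle rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_z <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
         3L, 3L, byrow = TRUE)
}

#' @rdname rotation_z
#' @export
rotation_x <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
         3L, 3L, byrow = TRUE)
}

#' @rdname rotation_z
#' @export
rotation_y <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
         3L, 3L, byrow = TRUE)
}

# concatenate meshes, offsetting face indices; labels filled with NA where
# absent in an input
merge_meshes <- function(meshes) {
  stopifnot(length(meshes) >= 1L)
  vs <- lapply(meshes, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, 0L)))
  fs <- mapply(function(m, o) m$faces + o, meshes, off[-length(off)],
               SIMPLIFY = FALSE)
  labs <- unlist(lapply(meshes, function(m) {
    if (is.null(m$labels)) rep(NA_character_, nrow(m$faces)) else m$labels
  }))
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), labels = labs,
                clean = FALSE)
}
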
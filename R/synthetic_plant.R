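# run code under a temporary RNG state (restores the caller's state)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic broadleaf plant
#'
#' Parametric description of a rosette-style broadleaf plant: a stem of
#' stacked internode cylinders rising from the soil plane (z = 0), leaves
#' with elliptic laminae attached at given heights, an optional apical stalk
#' carrying the plant top, and a square soil plate. The defaults describe the
#' bushy six-leaf succulent used throughout the package examples: leaf
#' lengths/widths/inclinations matching its directly measured traits, three
#' internodes of 18, 16 and 18 mm (radii 1.95, 1.75, 1.5 mm) and a plant top
#' at 98.7 mm.
#'
#' @param leaf_length per-leaf tip-to-base length (mm).
#' @param leaf_width per-leaf maximum width perpendicular to the tip-base
#'   axis (mm).
#' @param leaf_inclination per-leaf elevation of the tip-base chord above the
#'   horizontal (degrees).
#' @param leaf_azimuth per-leaf azimuth of the tip direction (degrees).
#' @param leaf_attach per-leaf attachment height on the stem (mm).
#' @param internode_length internode lengths from the soil surface up (mm).
#' @param internode_radius internode radii (mm); internode width (diameter)
#'   is twice this.
#' @param apex_height absolute height of the plant top (mm); realised as a
#'   thin apical stalk above the last node (set to the top node height to
#'   disable).
#' @param apex_radius radius of the apical stalk (mm).
#' @param soil_size side length of the square soil plate at z = 0 (mm).
#' @param resolution target mesh edge length (mm).
#' @param jitter relative radial jitter of the leaf outline (0 = exact
#'   ellipse).
#' @param seed seed for the outline jitter.
#' @return an object of class \code{plant_spec}.
#' @export
plant_spec <- function(leaf_length = c(49.1, 52.4, 58.2, 55.2, 42.9, 42.9),
                       leaf_width = c(34.3, 33.8, 42.6, 44.2, 28.9, 30.0),
                       leaf_inclination = c(20, 10, 3, 5, 10, 10),
                       leaf_azimuth = c(0, 180, 90, 270, 45, 225),
                       leaf_attach = c(18, 18, 34, 34, 52, 52),
                       internode_length = c(18, 16, 18),
                       internode_radius = c(1.95, 1.75, 1.5),
                       apex_height = 98.7,
                       apex_radius = 0.75,
                       soil_size = 270,
                       resolution = 3,
                       jitter = 0,
                       seed = 1L) {
  n <- length(leaf_length)
  spec <- list(
    leaf_length = leaf_length,
    leaf_width = rep_len(leaf_width, n),
    leaf_inclination = rep_len(leaf_inclination, n),
    leaf_azimuth = rep_len(leaf_azimuth, n),
    leaf_attach = rep_len(leaf_attach, n),
    internode_length = internode_length,
    internode_radius = rep_len(internode_radius, length(internode_length)),
    apex_height = apex_height,
    apex_radius = apex_radius,
    soil_size = soil_size,
    resolution = resolution,
    jitter = jitter,
    seed = seed)
  .validate_plant_spec(spec)
  structure(spec, class = "plant_spec")
}

.validate_plant_spec <- function(s) {
  num_pos <- function(x, nm) {
    if (length(x) && any(!is.finite(x) | x <= 0))
      stop("'", nm, "' must be positive")
  }
  num_pos(s$leaf_length, "leaf_length")
  num_pos(s$leaf_width, "leaf_width")
  num_pos(s$internode_length, "internode_length")
  num_pos(s$internode_radius, "internode_radius")
  num_pos(s$resolution, "resolution")
  if (any(s$leaf_inclination < 0 | s$leaf_inclination > 90))
    stop("'leaf_inclination' must be in [0, 90] degrees")
  if (length(s$leaf_attach) &&
      any(s$leaf_attach < 0 |
          s$leaf_attach > sum(s$internode_length) + 1e-9))
    stop("'leaf_attach' must lie on the stem")
  if (s$jitter < 0 || s$jitter >= 0.5) stop("'jitter' must be in [0, 0.5)")
  invisible(s)
}

#' @export
print.plant_spec <- function(x, ...) {
  cat("plant_spec:", length(x$leaf_length), "leaves,",
      length(x$internode_length), "internodes, top at",
      max(x$apex_height, sum(x$internode_length)), "mm\n")
  invisible(x)
}

#' Generate a single synthetic leaf with known ground truth
#'
#' Builds a triangulated elliptic lamina with optional radial outline jitter
#' and parabolic midrib droop, then tilts it to the requested inclination and
#' azimuth. The tip and base landmarks sit on the outline along the major
#' axis, the base at the attachment point. Ground-truth traits are computed
#' from the generated geometry itself: the area by exact summation of the
#' face areas, the length as the tip-base distance, the width as the maximal
#' lamina extent perpendicular to the tip-base axis, and the inclination as
#' the elevation of the tip-base chord.
#'
#' @param length tip-to-base length (mm).
#' @param width maximum width (mm).
#' @param inclination elevation of the tip-base chord (degrees).
#' @param azimuth azimuth of the tip direction (degrees).
#' @param attach 3D attachment point of the leaf base (mm).
#' @param droop midrib droop depth at the tip (mm, downwards; 0 = flat).
#' @param resolution target mesh edge length (mm).
#' @param jitter relative radial outline jitter.
#' @param seed jitter seed.
#' @param label organ label for the faces.
#' @return a list with components \code{mesh} (a
#'   \code{\link{triangle_mesh}}), \code{ground_truth} (one-row data frame)
#'   and \code{landmarks} (tip/base vertex indices and the attachment point).
#' @export
generate_leaf <- function(length, width, inclination = 0, azimuth = 0,
                          attach = c(0, 0, 0), droop = 0, resolution = 3,
                          jitter = 0, seed = NULL, label = "L1") {
  if (resolution <= 0) stop("'resolution' must be positive")
  if (resolution >= max(length, width))
    stop("'resolution' too coarse for a ", length, " x ", width, " mm leaf")
  a <- length / 2
  b <- width / 2
  n_t <- max(8L, 4L * ceiling(pi * (a + b) / 2 / resolution / 4))
  n_r <- max(2L, ceiling(max(a, b) / resolution))
  theta <- 2 * pi * (seq_len(n_t) - 1L) / n_t
  mult <- rep(1, n_t)
  if (jitter > 0) {
    mult <- with_seed(seed, 1 + jitter * stats::runif(n_t, -1, 1))
    # pin the major-axis directions so length stays exact
    mult[c(1L, n_t / 2L + 1L)] <- 1
  }
  # 2D lamina: base at the origin, tip at (length, 0)
  verts2 <- matrix(c(a, 0), 1L, 2L)
  for (i in seq_len(n_r)) {
    f <- i / n_r
    verts2 <- rbind(verts2,
                    cbind(a + f * mult * a * cos(theta),
                          f * mult * b * sin(theta)))
  }
  idx <- function(i, j) 1L + (i - 1L) * n_t + (j - 1L) %% n_t + 1L
  faces <- vector("list", n_r)
  j <- seq_len(n_t)
  faces[[1]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n_r - 1L))
    faces[[i + 1L]] <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  faces <- do.call(rbind, faces)
  z <- -droop * (verts2[, 1L] / length)^2
  verts <- cbind(verts2, z)
  tip_i <- idx(n_r, 1L)
  base_i <- idx(n_r, n_t / 2L + 1L)
  # move the base to the local origin, tilt, swing, translate
  verts <- verts - matrix(verts[base_i, ], nrow(verts), 3L, byrow = TRUE)
  rot <- rotation_z(azimuth) %*% rotation_y(-inclination)
  verts <- verts %*% t(rot) +
    matrix(attach, nrow(verts), 3L, byrow = TRUE)
  mesh <- triangle_mesh(verts, faces, labels = rep(label, nrow(faces)))
  tipv <- mesh$vertices[tip_i, ]
  basev <- mesh$vertices[base_i, ]
  chord <- tipv - basev
  len <- sqrt(sum(chord^2))
  gt <- data.frame(
    organ = label, type = "leaf",
    area_cm2 = sum(face_areas(mesh)) / 100,
    length_mm = len,
    width_mm = diff(range(verts2[, 2L])),
    inclination_deg = asin(min(1, abs(chord[3L]) / len)) * 180 / pi,
    height_mm = NA_real_,
    stringsAsFactors = FALSE)
  list(mesh = mesh,
       ground_truth = gt,
       landmarks = list(tip = tip_i, base = base_i, attach = attach))
}

# open cylinder between two heights; rings at bottom, middle and top so that
# a mid-height slab always contains vertices
.make_cylinder <- function(radius, z0, z1, label, sides = 16L) {
  theta <- 2 * pi * (seq_len(sides) - 1L) / sides
  zs <- c(z0, (z0 + z1) / 2, z1)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(theta), radius * sin(theta), z)))
  idx <- function(ring, j) (ring - 1L) * sides + (j - 1L) %% sides + 1L
  j <- seq_len(sides)
  faces <- do.call(rbind, lapply(1:2, function(r)
    rbind(cbind(idx(r, j), idx(r + 1L, j), idx(r + 1L, j + 1L)),
          cbind(idx(r, j), idx(r + 1L, j + 1L), idx(r, j + 1L)))))
  triangle_mesh(verts, faces, labels = rep(label, nrow(faces)))
}

.make_soil <- function(size) {
  h <- size / 2
  verts <- cbind(c(-h, h, h, -h), c(-h, -h, h, h), 0)
  faces <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  triangle_mesh(verts, faces, labels = rep("soil", 2L))
}

#' Generate a synthetic plant with known ground truth
#'
#' Assembles the plant described by a \code{\link{plant_spec}}: soil plate,
#' stacked internode cylinders, optional apical stalk and elliptic leaves,
#' every face carrying its organ label. Ground truth is filled by
#' construction (leaf traits from the generated laminae, internode heights
#' and diameters from the cylinder parameters, plant height from the highest
#' non-soil vertex).
#'
#' @param spec a \code{\link{plant_spec}}.
#' @return a list with \code{mesh} (labeled \code{\link{triangle_mesh}}),
#'   \code{ground_truth} (class \code{ground_truth}) and the spec.
#' @export
generate_plant <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  node_z <- cumsum(spec$internode_length)
  z0 <- c(0, node_z[-length(node_z)])
  parts <- list(.make_soil(spec$soil_size))
  stem_rows <- list()
  for (k in seq_along(spec$internode_length)) {
    lab <- paste0("stem", k)
    parts[[length(parts) + 1L]] <-
      .make_cylinder(spec$internode_radius[k], z0[k], node_z[k], lab)
    stem_rows[[k]] <- data.frame(
      organ = lab, type = "internode", area_cm2 = NA_real_,
      length_mm = NA_real_, width_mm = 2 * spec$internode_radius[k],
      inclination_deg = NA_real_, height_mm = spec$internode_length[k],
      stringsAsFactors = FALSE)
  }
  if (spec$apex_height > max(node_z) + 1e-9)
    parts[[length(parts) + 1L]] <-
      .make_cylinder(spec$apex_radius, max(node_z), spec$apex_height, "apex")
  leaf_rows <- list()
  landmarks <- list()
  offset <- sum(vapply(parts, n_vertices, 0L))
  for (i in seq_along(spec$leaf_length)) {
    h <- spec$leaf_attach[i]
    k <- findInterval(h, c(0, node_z), rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(spec$internode_radius))
    r <- spec$internode_radius[k] + 0.1
    az <- spec$leaf_azimuth[i]
    attach <- c(r * cos(az * pi / 180), r * sin(az * pi / 180), h)
    leaf <- generate_leaf(spec$leaf_length[i], spec$leaf_width[i],
                          inclination = spec$leaf_inclination[i],
                          azimuth = az, attach = attach,
                          resolution = spec$resolution,
                          jitter = spec$jitter,
                          seed = if (is.null(spec$seed)) NULL
                                 else spec$seed + i,
                          label = paste0("L", i))
    leaf_rows[[i]] <- leaf$ground_truth
    landmarks[[paste0("L", i)]] <-
      list(tip = leaf$landmarks$tip + offset,
           base = leaf$landmarks$base + offset,
           attach = attach)
    offset <- offset + n_vertices(leaf$mesh)
    parts[[length(parts) + 1L]] <- leaf$mesh
  }
  mesh <- merge_meshes(parts)
  organs <- rbind(do.call(rbind, leaf_rows), do.call(rbind, stem_rows))
  nonsoil <- mesh$labels != "soil"
  vs <- unique(as.vector(mesh$faces[nonsoil, , drop = FALSE]))
  gt <- structure(list(organs = organs,
                       plant_height = max(mesh$vertices[vs, 3L]),
                       node_z = node_z,
                       landmarks = landmarks),
                  class = "ground_truth")
  list(mesh = mesh, ground_truth = gt, spec = spec)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth: plant height", sprintf("%.1f", x$plant_height), "mm\n")
  print(x$organs, row.names = FALSE)
  invisible(x)
}

#' Write / read ground truth as CSV
#'
#' One row per organ plus a \code{plant} row carrying the plant height and a
#' \code{node} row per internode boundary; leaf landmark vertex indices and
#' attachment coordinates are stored as extra columns.
#'
#' @param gt a \code{ground_truth}.
#' @param path CSV file path.
#' @return \code{path} (write) or a \code{ground_truth} (read).
#' @export
write_ground_truth <- function(gt, path) {
  org <- gt$organs
  org$tip_vertex <- NA_integer_
  org$base_vertex <- NA_integer_
  org$attach_x <- NA_real_; org$attach_y <- NA_real_; org$attach_z <- NA_real_
  for (nm in names(gt$landmarks)) {
    i <- match(nm, org$organ)
    lm <- gt$landmarks[[nm]]
    org$tip_vertex[i] <- lm$tip
    org$base_vertex[i] <- lm$base
    org$attach_x[i] <- lm$attach[1L]
    org$attach_y[i] <- lm$attach[2L]
    org$attach_z[i] <- lm$attach[3L]
  }
  extra <- org[0, ]
  extra[1, "organ"] <- "plant"
  extra[1, "type"] <- "plant"
  extra[1, "height_mm"] <- gt$plant_height
  for (k in seq_along(gt$node_z)) {
    extra[k + 1L, "organ"] <- paste0("node", k)
    extra[k + 1L, "type"] <- "node"
    extra[k + 1L, "height_mm"] <- gt$node_z[k]
  }
  utils::write.csv(rbind(org, extra), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  organs <- df[df$type %in% c("leaf", "internode"), , drop = FALSE]
  landmarks <- list()
  for (i in which(!is.na(organs$tip_vertex))) {
    landmarks[[organs$organ[i]]] <-
      list(tip = organs$tip_vertex[i], base = organs$base_vertex[i],
           attach = c(organs$attach_x[i], organs$attach_y[i],
                      organs$attach_z[i]))
  }
  keep <- c("organ", "type", "area_cm2", "length_mm", "width_mm",
            "inclination_deg", "height_mm")
  structure(list(organs = organs[, keep],
                 plant_height = df$height_mm[df$type == "plant"][1L],
                 node_z = df$height_mm[df$type == "node"],
                 landmarks = landmarks),
            class = "ground_truth")
}
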
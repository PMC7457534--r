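# algebraic (Kasa) least-squares circle fit; returns the centre, or the
# fallback when the system is ill-conditioned or under-determined
.fit_circle_center <- function(x, y, fallback) {
  if (length(x) < 3L) return(fallback)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) return(fallback)
  fit[1:2]
}

# faces of x belonging to one organ label, as a triangle_mesh; error when
# the organ is absent
.organ_mesh <- function(x, organ) {
  mesh <- as_triangle_mesh(x)
  if (is.null(mesh$labels)) stop("model carries no organ labels")
  idx <- which(mesh$labels == organ)
  if (length(idx) == 0L) stop("no faces labeled '", organ, "'")
  triangle_mesh(mesh$vertices, mesh$faces[idx, , drop = FALSE],
                labels = mesh$labels[idx], clean = FALSE)
}

#' Leaf area
#'
#' Sum of the mesh face areas of one leaf, reported in cm^2.
#'
#' @param x a labeled \code{\link{triangle_mesh}}, \code{partial_model} or
#'   \code{merged_model}.
#' @param organ leaf label (e.g. \code{"L1"}).
#' @return area in cm^2.
#' @export
leaf_area <- function(x, organ) {
  sum(face_areas(.organ_mesh(x, organ))) / 100
}

# boundary vertices of a mesh subset: vertices on edges used by exactly one
# face
.boundary_vertices <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  once <- names(cnt)[cnt == 1L]
  unique(as.vector(e[key %in% once, , drop = FALSE]))
}

#' Locate the leaf tip and base
#'
#' The base is the leaf-boundary vertex nearest the attachment point (where
#' the petiole meets the stem); the tip is the boundary vertex farthest from
#' the base. Ties within 1e-6 mm resolve to the lower vertex index with a
#' warning.
#'
#' @inheritParams leaf_area
#' @param attachment 3D attachment point (mm), expected within 2 mm of the
#'   leaf boundary.
#' @return list with \code{tip} and \code{base} (vertex indices into the
#'   model's vertex set) and their coordinates.
#' @export
detect_tip_base <- function(x, organ, attachment) {
  mesh <- .organ_mesh(x, organ)
  bd <- .boundary_vertices(mesh)
  if (length(bd) < 2L) stop("leaf boundary has fewer than 2 vertices")
  V <- mesh$vertices
  d_att <- sqrt(colSums((t(V[bd, , drop = FALSE]) - attachment)^2))
  if (min(d_att) > 2)
    warning(sprintf("attachment point is %.1f mm from the leaf boundary",
                    min(d_att)))
  base <- bd[which.min(d_att)]
  d_tip <- sqrt(colSums((t(V[bd, , drop = FALSE]) - V[base, ])^2))
  mx <- max(d_tip)
  cand <- bd[d_tip > mx - 1e-6]
  if (length(cand) > 1L)
    warning("ambiguous leaf tip; picking the lowest vertex index")
  tip <- min(cand)
  list(tip = tip, base = base, tip_point = V[tip, ], base_point = V[base, ])
}

#' Leaf length
#'
#' Euclidean distance of the straight chord connecting the leaf tip and the
#' leaf base.
#'
#' @param tip,base 3D points (mm).
#' @return length in mm.
#' @export
leaf_length <- function(tip, base) {
  d <- sqrt(sum((tip - base)^2))
  if (d < 1e-9) stop("tip and base coincide")
  d
}

#' Leaf width
#'
#' Width of the lamina perpendicular to the tip-base axis: the vertices are
#' projected onto the best-fit lamina plane and the width is the extent
#' along the in-plane direction perpendicular to the projected tip-base
#' axis.
#'
#' @inheritParams leaf_area
#' @param tip,base 3D tip and base points (mm).
#' @return width in mm.
#' @export
leaf_width <- function(x, organ, tip, base) {
  mesh <- .organ_mesh(x, organ)
  V <- mesh$vertices[sort(unique(as.vector(mesh$faces))), , drop = FALSE]
  ctr <- colMeans(V)
  Vc <- sweep(V, 2L, ctr)
  sv <- svd(Vc, nu = 0L, nv = 3L)
  if (sv$d[2L] < 1e-9) stop("degenerate lamina: vertices are collinear")
  plane <- sv$v[, 1:2, drop = FALSE]  # orthonormal basis of the lamina plane
  axis2 <- as.vector(t(plane) %*% (tip - base))
  if (sqrt(sum(axis2^2)) < 1e-9)
    stop("tip-base axis is perpendicular to the lamina plane")
  axis2 <- axis2 / sqrt(sum(axis2^2))
  perp2 <- c(-axis2[2L], axis2[1L])
  w <- (Vc %*% plane) %*% perp2
  diff(range(w))
}

#' Leaf inclination angle
#'
#' Elevation of the tip-base chord above the horizontal — the complement of
#' the zenith angle of the tip-to-base vector — in [0, 90] degrees.
#'
#' @param tip,base 3D points (mm).
#' @return angle in degrees.
#' @export
leaf_inclination <- function(tip, base) {
  d <- tip - base
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("tip and base coincide")
  asin(min(1, abs(d[3L]) / len)) * 180 / pi
}

#' Plant height
#'
#' Absolute Z difference between the top of the plant and the soil surface
#' (z = 0 by convention); soil faces are excluded.
#'
#' @inheritParams leaf_area
#' @return height in mm.
#' @export
plant_height <- function(x) {
  mesh <- as_triangle_mesh(x)
  keep <- if (is.null(mesh$labels)) rep(TRUE, n_faces(mesh))
          else mesh$labels != "soil"
  if (!any(keep)) stop("no non-soil faces")
  vs <- unique(as.vector(mesh$faces[keep, , drop = FALSE]))
  max(mesh$vertices[vs, 3L])
}

#' Stem internode heights and widths
#'
#' Internode height is the length of each internode (difference of
#' consecutive node heights, the first node measured from the soil surface).
#' Internode width is the diameter of the stem cross-section at the
#' internode mid-height: twice the median radial distance of the stem
#' vertices inside a +/- 0.5 mm slab around the mid-height from the fitted
#' stem axis at that height. The axis point is fitted to the slab's xy
#' coordinates by an algebraic least-squares circle fit, which stays
#' unbiased when only an arc of the circumference was reconstructed (a
#' plain vertex centroid would drift towards the detected side); with
#' fewer than three slab vertices the fit falls back to the median xy of
#' all stem vertices. An internode with no detected faces or an empty slab
#' is reported NG (missing, \code{NA}).
#'
#' @inheritParams leaf_area
#' @param node_z node heights (mm), strictly increasing, excluding 0.
#' @param slab half-thickness of the mid-height slab (mm).
#' @return data frame with one row per internode: \code{organ},
#'   \code{height_mm}, \code{width_mm}, \code{ng}.
#' @export
stem_internode_traits <- function(x, node_z, slab = 0.5) {
  if (any(node_z <= 0) || any(diff(node_z) <= 0))
    stop("'node_z' must be strictly increasing and positive")
  mesh <- as_triangle_mesh(x)
  if (is.null(mesh$labels)) stop("model carries no organ labels")
  z0 <- c(0, node_z[-length(node_z)])
  n <- length(node_z)
  stem_v <- unique(as.vector(
    mesh$faces[grepl("^stem", mesh$labels), , drop = FALSE]))
  axis_xy <- if (length(stem_v))
    c(stats::median(mesh$vertices[stem_v, 1L]),
      stats::median(mesh$vertices[stem_v, 2L]))
  else c(0, 0)
  out <- data.frame(organ = paste0("stem", seq_len(n)),
                    height_mm = node_z - z0,
                    width_mm = NA_real_,
                    ng = TRUE, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    lab <- paste0("stem", k)
    idx <- which(mesh$labels == lab)
    if (length(idx) == 0L) next
    vs <- unique(as.vector(mesh$faces[idx, , drop = FALSE]))
    V <- mesh$vertices[vs, , drop = FALSE]
    mid <- (z0[k] + node_z[k]) / 2
    in_slab <- abs(V[, 3L] - mid) <= slab
    if (!any(in_slab)) next
    ctr <- .fit_circle_center(V[in_slab, 1L], V[in_slab, 2L], axis_xy)
    r <- sqrt((V[in_slab, 1L] - ctr[1L])^2 +
              (V[in_slab, 2L] - ctr[2L])^2)
    out$width_mm[k] <- 2 * stats::median(r)
    out$ng[k] <- FALSE
  }
  out$height_mm[out$ng] <- NA_real_
  out
}

#' Extract the full trait set of a plant model
#'
#' Runs every trait extractor over a labeled model: per-leaf area, length,
#' width and inclination (tip/base located from ground-truth landmarks when
#' the landmark vertices were reconstructed, otherwise re-detected from the
#' leaf boundary and the attachment point), per-internode height and width,
#' and the plant height. Leaves or internodes missing from the model are
#' reported NG.
#'
#' @inheritParams leaf_area
#' @param ground_truth a \code{ground_truth} providing landmarks and node
#'   heights.
#' @return an object of class \code{trait_set}: a data frame of per-organ
#'   traits plus the plant height.
#' @export
extract_traits <- function(x, ground_truth) {
  mesh <- as_triangle_mesh(x)
  gt <- ground_truth
  leaves <- gt$organs$organ[gt$organs$type == "leaf"]
  detected_v <- sort(unique(as.vector(mesh$faces)))
  rows <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    organ <- leaves[i]
    lm <- gt$landmarks[[organ]]
    row <- data.frame(organ = organ, type = "leaf", area_cm2 = NA_real_,
                      length_mm = NA_real_, width_mm = NA_real_,
                      inclination_deg = NA_real_, height_mm = NA_real_,
                      ng = TRUE, stringsAsFactors = FALSE)
    has_faces <- !is.null(mesh$labels) && any(mesh$labels == organ)
    if (has_faces) {
      row$area_cm2 <- leaf_area(mesh, organ)
      tb <- NULL
      if (!is.null(lm) && all(c(lm$tip, lm$base) %in% detected_v)) {
        tb <- list(tip_point = mesh$vertices[lm$tip, ],
                   base_point = mesh$vertices[lm$base, ])
      } else if (!is.null(lm)) {
        tb <- tryCatch(detect_tip_base(mesh, organ, lm$attach),
                       error = function(e) NULL)
      }
      if (!is.null(tb)) {
        row$length_mm <- leaf_length(tb$tip_point, tb$base_point)
        row$width_mm <- tryCatch(
          leaf_width(mesh, organ, tb$tip_point, tb$base_point),
          error = function(e) NA_real_)
        row$inclination_deg <- leaf_inclination(tb$tip_point, tb$base_point)
        row$ng <- FALSE
      }
    }
    rows[[i]] <- row
  }
  leaf_df <- do.call(rbind, rows)
  stem_df <- stem_internode_traits(mesh, gt$node_z)
  stem_df <- data.frame(organ = stem_df$organ, type = "internode",
                        area_cm2 = NA_real_, length_mm = NA_real_,
                        width_mm = stem_df$width_mm,
                        inclination_deg = NA_real_,
                        height_mm = stem_df$height_mm,
                        ng = stem_df$ng, stringsAsFactors = FALSE)
  ph <- tryCatch(plant_height(mesh), error = function(e) NA_real_)
  structure(list(organs = rbind(leaf_df, stem_df), plant_height = ph),
            class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat("trait_set: plant height",
      sprintf("%.1f mm", x$plant_height), "\n")
  print(x$organs, row.names = FALSE)
  invisible(x)
}
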
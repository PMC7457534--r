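#' Merge per-VZA partial models (Method 1)
#'
#' Union of the detected face sets of several partial reconstructions of the
#' same scene; each vertex seen by more than one camera is fused by
#' inverse-variance weighting of the per-camera perturbed positions (weights
#' \code{1/sigma^2}), which reduces to plain averaging for equal noise
#' scales and yields a fused scale of \code{sigma/sqrt(k)} for \code{k}
#' equal contributors. Duplicate partials from the same camera are counted
#' once, so the merge is idempotent.
#'
#' @param partials list of \code{partial_model} from the same scene.
#' @return an object of class \code{merged_model} (method tag \code{"M1"}).
#' @export
merge_method1 <- function(partials) {
  if (length(partials) == 0L) stop("no partial models")
  stopifnot(all(vapply(partials, inherits, TRUE, "partial_model")))
  nf <- vapply(partials, function(p) nrow(p$scene_faces), 0L)
  if (length(unique(nf)) != 1L)
    stop("partial models come from different scenes")
  cams <- vapply(partials, `[[`, "", "camera")
  partials <- partials[!duplicated(cams)]
  faces <- sort(unique(unlist(lapply(partials, `[[`, "faces"))))
  ref <- partials[[1L]]
  nv <- nrow(ref$vertices)
  wsum <- numeric(nv)
  acc <- matrix(0, nv, 3L)
  contrib <- matrix(FALSE, nv, length(partials))
  for (k in seq_along(partials)) {
    p <- partials[[k]]
    det <- which(!is.na(p$sigma))
    contrib[det, k] <- TRUE
    w <- 1 / pmax(p$sigma[det], 1e-9)^2
    wsum[det] <- wsum[det] + w
    acc[det, ] <- acc[det, ] + p$vertices[det, , drop = FALSE] * w
  }
  seen <- wsum > 0
  vertices <- ref$vertices
  vertices[seen, ] <- acc[seen, , drop = FALSE] / wsum[seen]
  sigma <- rep(NA_real_, nv)
  sigma[seen] <- 1 / sqrt(wsum[seen])
  provenance <- lapply(faces, function(f) {
    vapply(partials, function(p) f %in% p$faces, TRUE)
  })
  prov <- do.call(rbind, provenance)
  colnames(prov) <- vapply(partials, `[[`, "", "camera")
  structure(list(method = "M1",
                 cameras = colnames(prov),
                 faces = faces,
                 vertices = vertices,
                 sigma = sigma,
                 provenance = prov,
                 scene_faces = ref$scene_faces,
                 scene_vertices = ref$scene_vertices,
                 scene_labels = ref$scene_labels),
            class = "merged_model")
}

#' @export
print.merged_model <- function(x, ...) {
  cat("merged_model (", x$method, ") from ",
      paste(x$cameras, collapse = ", "), ": ",
      length(x$faces), " of ", nrow(x$scene_faces), " faces\n", sep = "")
  invisible(x)
}

#' @export
as_triangle_mesh.merged_model <- function(x) {
  triangle_mesh(x$vertices, x$scene_faces[x$faces, , drop = FALSE],
                labels = if (is.null(x$scene_labels)) NULL
                         else x$scene_labels[x$faces],
                clean = FALSE)
}

#' Joint reconstruction from pooled images (Method 2)
#'
#' Emulates building one model directly from the pooled images of all
#' selected cameras. Pooling does not add vertical overlap: with one camera
#' per 12 degrees of zenith, features seen from a single camera only cannot
#' be matched across the sparse vertical baseline, so a face is
#' reconstructed only when (a) some camera gives it a consecutive-visible
#' run of at least \code{n_min} frames and (b) it is visible, in any frame,
#' from at least two distinct cameras. Vertex fusion is as in Method 1 over
#' the qualifying cameras. By construction the detected set is a subset of
#' the Method 1 set over the same cameras.
#'
#' @param scene a \code{\link{triangle_mesh}}.
#' @param rig a \code{\link{camera_rig}}.
#' @param cameras at least two camera indices or ids.
#' @param schedule a \code{\link{turntable_schedule}}.
#' @param noise a \code{\link{noise_model}}.
#' @param partials optional precomputed per-camera partial models (avoids
#'   re-running the visibility simulation).
#' @return an object of class \code{merged_model} (method tag \code{"M2"}).
#' @export
joint_model_method2 <- function(scene, rig, cameras, schedule, noise,
                                partials = NULL) {
  if (length(cameras) < 2L) stop("Method 2 needs at least 2 cameras")
  if (is.null(partials))
    partials <- lapply(cameras, function(cam)
      reconstruct_single_vza(scene, rig, cam, schedule, noise))
  m1 <- merge_method1(partials)
  nsee <- rowSums(vapply(partials, function(p) rowSums(p$visible) > 0,
                         logical(nrow(m1$scene_faces))))
  keep <- m1$faces[nsee[m1$faces] >= 2L]
  out <- m1
  out$method <- "M2"
  out$faces <- keep
  out$provenance <- m1$provenance[match(keep, m1$faces), , drop = FALSE]
  out
}

#' Per-organ completeness of a model
#'
#' Detected area of each organ as a percentage of its reference (directly
#' measured) area, reported at 0.1 percent precision. Completeness is a
#' coverage measure: each detected face contributes its true (unperturbed
#' scene) area, so reconstruction noise can neither inflate nor shrink it
#' and adding a camera can only increase it.
#'
#' @param model a \code{partial_model} or \code{merged_model}.
#' @param reference named numeric vector of reference areas (mm^2) per
#'   organ label.
#' @return named numeric vector of percentages.
#' @export
completeness <- function(model, reference) {
  if (any(reference <= 0)) stop("reference areas must be positive")
  labels <- model$scene_labels
  if (is.null(labels)) stop("model carries no organ labels")
  if (!all(names(reference) %in% labels))
    stop("unknown organ label in 'reference'")
  V <- if (is.null(model$scene_vertices)) model$vertices
       else model$scene_vertices
  ar <- face_areas(list(vertices = V, faces = model$scene_faces))
  out <- vapply(names(reference), function(org) {
    det <- intersect(model$faces, which(labels == org))
    sum(ar[det]) / reference[[org]] * 100
  }, 0)
  round_half_up(out, 1)
}

#' Run and compare both whole-plant reconstruction strategies
#'
#' Simulates every selected camera's partial model once, fuses them by
#' Method 1 (merge the per-VZA models) and by Method 2 (joint model from the
#' pooled images), extracts the trait set from each fused model and builds
#' the error tables against ground truth, flagging NG organs.
#'
#' @inheritParams joint_model_method2
#' @param ground_truth a \code{ground_truth} for the scene.
#' @return an object of class \code{method_comparison}: partial models, both
#'   merged models, per-method trait sets, error tables, per-organ
#'   completeness and NG counts.
#' @export
compare_methods <- function(scene, ground_truth, rig, cameras, schedule,
                            noise) {
  partials <- lapply(cameras, function(cam)
    reconstruct_single_vza(scene, rig, cam, schedule, noise))
  m1 <- merge_method1(partials)
  m2 <- joint_model_method2(scene, rig, cameras, schedule, noise,
                            partials = partials)
  t1 <- extract_traits(m1, ground_truth)
  t2 <- extract_traits(m2, ground_truth)
  e1 <- build_error_table(t1, ground_truth, method = "M1")
  e2 <- build_error_table(t2, ground_truth, method = "M2")
  leaves <- ground_truth$organs$organ[ground_truth$organs$type == "leaf"]
  ref <- stats::setNames(ground_truth$organs$area_cm2[
    match(leaves, ground_truth$organs$organ)] * 100, leaves)
  structure(list(partials = partials, m1 = m1, m2 = m2,
                 traits = list(M1 = t1, M2 = t2),
                 errors = list(M1 = e1, M2 = e2),
                 completeness = list(M1 = completeness(m1, ref),
                                     M2 = completeness(m2, ref)),
                 ng = c(M1 = sum(e1$entries$ng), M2 = sum(e2$entries$ng))),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison:",
      length(x$m1$faces), "faces (M1) vs", length(x$m2$faces),
      "faces (M2);", "NG entries M1:", x$ng[["M1"]],
      "M2:", x$ng[["M2"]], "\n")
  invisible(x)
}

#' Tabulate a method comparison
#'
#' One row per organ and trait with the direct measurement, both methods'
#' estimates, error percentages, errors over plant height and NG flags.
#'
#' @param x a \code{method_comparison}.
#' @param ... unused.
#' @return a data frame.
#' @export
as.data.frame.method_comparison <- function(x, ...) {
  e1 <- x$errors$M1$entries
  e2 <- x$errors$M2$entries
  data.frame(organ = e1$organ, trait = e1$trait, direct = e1$measured,
             m1_estimate = e1$estimated,
             m1_error_pct = round_half_up(e1$error_pct, 1),
             m1_error_over_height_pct =
               round_half_up(e1$error_over_height_pct, 1),
             m1_ng = e1$ng,
             m2_estimate = e2$estimated,
             m2_error_pct = round_half_up(e2$error_pct, 1),
             m2_error_over_height_pct =
               round_half_up(e2$error_over_height_pct, 1),
             m2_ng = e2$ng,
             stringsAsFactors = FALSE)
}
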
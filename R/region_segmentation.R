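#' Cumulative detected area over mesh inclination angle
#'
#' Sorts the detected faces by their mesh inclination angle (the zenith angle
#' of the face normal folded to [0, 90] degrees) and accumulates their areas,
#' giving the curve that relates an inclination threshold to the detected
#' area at or below it.
#'
#' @param x a \code{\link{triangle_mesh}}, \code{partial_model} or
#'   \code{merged_model}.
#' @param organ optional organ label restricting the faces entering the
#'   statistic (e.g. \code{"L1"} to exclude the soil plate and other
#'   organs).
#' @return an object of class \code{cumulative_area_curve} with sorted
#'   \code{angle} (degrees), \code{area} (cumulative, mm^2) and the
#'   \code{total} detected area.
#' @export
cumulative_area_curve <- function(x, organ = NULL) {
  mesh <- .subset_organ(as_triangle_mesh(x), organ)
  if (n_faces(mesh) == 0L) stop("empty model")
  ang <- face_inclinations(mesh)
  ar <- face_areas(mesh)
  o <- order(ang)
  structure(list(angle = ang[o], area = cumsum(ar[o]), total = sum(ar)),
            class = "cumulative_area_curve")
}

# subset a mesh to one organ label; empty subset allowed
.subset_organ <- function(mesh, organ) {
  if (is.null(organ)) return(mesh)
  if (is.null(mesh$labels)) stop("model carries no organ labels")
  idx <- which(mesh$labels == organ)
  triangle_mesh(mesh$vertices, mesh$faces[idx, , drop = FALSE],
                labels = mesh$labels[idx], clean = FALSE)
}

#' @export
print.cumulative_area_curve <- function(x, ...) {
  cat("cumulative_area_curve:", length(x$angle), "faces, total",
      sprintf("%.1f mm^2", x$total), "\n")
  invisible(x)
}

#' @export
plot.cumulative_area_curve <- function(x, ...) {
  graphics::plot(x$angle, 100 * x$area / x$total, type = "s",
                 xlab = "mesh inclination angle (deg)",
                 ylab = "cumulative area (% of detected)", ...)
  invisible(x)
}

#' Determine the stability threshold from a reference model
#'
#' The threshold is the smallest inclination angle at which the cumulative
#' detected area reaches the directly measured organ area — the angle above
#' which the reference (most complete) model only adds spurious, steep
#' mesh: those faces are what the segmentation later calls unstable. If the
#' curve never reaches the measured area the threshold saturates at 90
#' degrees with a shortfall warning.
#'
#' @param curve a \code{\link{cumulative_area_curve}}.
#' @param measured_area directly measured organ area (mm^2, > 0).
#' @return threshold angle in degrees.
#' @export
determine_threshold <- function(curve, measured_area) {
  if (!is.numeric(measured_area) || measured_area <= 0)
    stop("'measured_area' must be positive")
  i <- which(curve$area >= measured_area - 1e-9)
  if (length(i) == 0L) {
    warning(sprintf(
      "detected area (%.1f mm^2) falls short of the measured area (%.1f mm^2)",
      curve$total, measured_area))
    return(90)
  }
  curve$angle[i[1L]]
}

#' Segment a model into stable, unstable and undetected regions
#'
#' Detected faces at or below the inclination threshold form the stable
#' region, detected faces above it the unstable region, and the area deficit
#' against the directly measured organ area the undetected region
#' (\code{max(0, measured - detected)}; when noise inflates the detected
#' area beyond the measurement the undetected area is zero). Fractions are
#' taken over \code{detected + undetected} so the three parts partition 1.
#'
#' @param x a \code{\link{triangle_mesh}}, \code{partial_model} or
#'   \code{merged_model}.
#' @param measured_area directly measured area (mm^2, > 0).
#' @param threshold inclination threshold T in degrees (default 45).
#' @param organ optional organ label restricting the segmentation to one
#'   organ (undetected area is then this organ's deficit).
#' @param camera,vza optional provenance carried into the report.
#' @return an object of class \code{region_report}.
#' @export
classify_regions <- function(x, measured_area, threshold = 45,
                             organ = NULL, camera = NULL, vza = NULL) {
  if (!is.numeric(measured_area) || measured_area <= 0)
    stop("'measured_area' must be positive")
  mesh <- .subset_organ(as_triangle_mesh(x), organ)
  if (is.null(camera) && !is.null(x$camera)) camera <- x$camera
  if (is.null(vza) && !is.null(x$vza)) vza <- x$vza
  ar <- face_areas(mesh)
  ang <- face_inclinations(mesh)
  stable <- sum(ar[ang <= threshold])
  unstable <- sum(ar[ang > threshold])
  detected <- stable + unstable
  undetected <- max(0, measured_area - detected)
  denom <- detected + undetected
  structure(list(stable_area = stable, unstable_area = unstable,
                 undetected_area = undetected, detected_area = detected,
                 measured_area = measured_area, threshold = threshold,
                 stable_frac = stable / denom,
                 unstable_frac = unstable / denom,
                 undetected_frac = undetected / denom,
                 camera = camera, vza = vza),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  if (!is.null(x$camera))
    cat(x$camera, sprintf("(VZA %g deg): ", x$vza))
  cat(sprintf(
    "stable %.1f%%, unstable %.1f%%, undetected %.1f%% (T = %g deg)\n",
    100 * x$stable_frac, 100 * x$unstable_frac, 100 * x$undetected_frac,
    x$threshold))
  invisible(x)
}

#' @export
as.data.frame.region_report <- function(x, ...) {
  data.frame(camera = if (is.null(x$camera)) NA_character_ else x$camera,
             vza = if (is.null(x$vza)) NA_real_ else x$vza,
             stable_pct = 100 * x$stable_frac,
             unstable_pct = 100 * x$unstable_frac,
             undetected_pct = 100 * x$undetected_frac,
             stable_area_mm2 = x$stable_area,
             unstable_area_mm2 = x$unstable_area,
             undetected_area_mm2 = x$undetected_area,
             measured_area_mm2 = x$measured_area,
             threshold_deg = x$threshold,
             stringsAsFactors = FALSE)
}

#' Select the optimum viewing zenith angles
#'
#' A camera qualifies when its model's stable fraction is at least
#' \code{stable_min} and its unstable and undetected fractions stay within
#' \code{unstable_max} and \code{undetected_max} (all in percent). Returns
#' the qualifying cameras and the VZA range they span; an empty selection
#' produces a warning, not an error.
#'
#' @param reports list of \code{region_report}, one per camera.
#' @param stable_min minimum stable area percentage (default 95).
#' @param unstable_max maximum unstable area percentage (default 2.5).
#' @param undetected_max maximum undetected area percentage (default 2).
#' @return a list with \code{cameras} (ids), \code{index} (positions in
#'   \code{reports}), \code{vza_range} and the per-camera percentage table.
#' @export
select_optimum_vzas <- function(reports, stable_min = 95,
                                unstable_max = 2.5, undetected_max = 2) {
  if (length(reports) == 0L) stop("no reports")
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  ok <- tab$stable_pct >= stable_min &
    tab$unstable_pct <= unstable_max &
    tab$undetected_pct <= undetected_max
  if (!any(ok)) warning("no camera meets the selection criteria")
  list(cameras = tab$camera[ok],
       index = which(ok),
       vza_range = if (any(ok)) range(tab$vza[ok]) else numeric(0),
       table = tab)
}

#' Write per-face region labels to a labeled PLY
#'
#' Writes the scene mesh with each face tagged \code{stable},
#' \code{unstable} or \code{undetected} for visual inspection of the
#' segmentation. Undetected faces are those of the reference scene missing
#' from the model.
#'
#' @param model a \code{partial_model} or \code{merged_model}.
#' @param scene the full reference \code{\link{triangle_mesh}}.
#' @param path output PLY path.
#' @param threshold inclination threshold (degrees).
#' @return \code{path}, invisibly.
#' @export
write_region_mesh <- function(model, scene, path, threshold = 45) {
  mesh <- as_triangle_mesh(model)
  ang <- face_inclinations(mesh)
  lab <- rep("undetected", n_faces(scene))
  lab[model$faces] <- ifelse(ang <= threshold, "stable", "unstable")
  out <- scene
  out$vertices <- model$vertices
  out$labels <- lab
  write_mesh(out, path)
}
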
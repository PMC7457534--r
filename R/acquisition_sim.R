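#' Multi-camera rig geometry
#'
#' Cameras on a vertical arc, each aimed at the scene centre on the
#' turntable rotation axis. Camera \code{i} sits at the viewing zenith angle
#' (VZA) \code{vza[i]}, measured from the zenith, at distance \code{range}
#' from the centre. The default ten cameras are spaced 12 degrees apart
#' starting at 0 (so C2 = 12 deg and C6 = 60 deg) at a range of 1 m.
#'
#' \code{max_incidence} is the largest angle (degrees) between a face normal
#' and the viewing ray at which the surface still yields usable image
#' texture: beyond it the face is foreshortened to a sliver and produces no
#' matchable features, so it does not count as seen. Both lamina sides
#' count (leaves are thin surfaces), hence the angle is measured against the
#' folded normal.
#'
#' @param n_cameras number of cameras.
#' @param vza viewing zenith angles (degrees, strictly increasing, in
#'   [0, 120)).
#' @param range camera-to-centre distance (mm).
#' @param center scene centre on the rotation axis (mm); x and y must be 0.
#' @param max_incidence foreshortening cutoff (degrees).
#' @return an object of class \code{camera_rig}.
#' @export
camera_rig <- function(n_cameras = 10L, vza = 12 * (seq_len(n_cameras) - 1L),
                       range = 1000, center = c(0, 0, 0),
                       max_incidence = 70) {
  if (any(vza < 0 | vza >= 120)) stop("'vza' must be in [0, 120) degrees")
  if (any(diff(vza) <= 0)) stop("'vza' must be strictly increasing")
  if (range <= 0) stop("'range' must be positive")
  if (any(abs(center[1:2]) > 1e-9))
    stop("scene centre must lie on the rotation axis (x = y = 0)")
  if (max_incidence <= 0 || max_incidence > 90)
    stop("'max_incidence' must be in (0, 90] degrees")
  a <- vza * pi / 180
  pos <- cbind(range * sin(a), 0, center[3L] + range * cos(a))
  structure(list(vza = vza, range = range, center = center,
                 max_incidence = max_incidence, positions = pos,
                 ids = paste0("C", seq_along(vza))),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat("camera_rig:", length(x$vza), "cameras at VZA",
      paste0(x$vza, collapse = ", "), "deg; range", x$range, "mm\n")
  invisible(x)
}

#' Turntable schedule
#'
#' Frame rotation angles of the plant about +Z. The default follows the
#' rig's acquisition protocol: one frame per 9 degrees, 41 frames per full
#' rotation, so the first and last frame coincide in pose and there are 40
#' distinct poses. Consecutive-visibility runs are computed on the cyclic
#' sequence of distinct poses.
#'
#' @param n_frames number of frames.
#' @param step rotation step between frames (degrees).
#' @return an object of class \code{turntable_schedule}.
#' @export
turntable_schedule <- function(n_frames = 41L, step = 9) {
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  angles <- (seq_len(n_frames) - 1L) * step
  if (max(angles) < 360 - 1e-9 && n_frames > 1L)
    warning("schedule does not cover a full rotation")
  pose_angle <- round(angles %% 360, 9)
  poses <- unique(pose_angle)
  structure(list(n_frames = as.integer(n_frames), step = step,
                 angles = angles, poses = poses,
                 frame_pose = match(pose_angle, poses)),
            class = "turntable_schedule")
}

#' @export
print.turntable_schedule <- function(x, ...) {
  cat("turntable_schedule:", x$n_frames, "frames,", x$step,
      "deg step,", length(x$poses), "distinct poses\n")
  invisible(x)
}

#' Reconstruction fidelity model
#'
#' Governs which surface patches survive the structure-from-motion pipeline
#' and how precisely they are placed. A patch is reconstructed only when it
#' stays visible for at least \code{n_min} consecutive frames (the feature
#' matcher needs a run of overlapping views). A reconstructed vertex is
#' perturbed along its mean viewing ray by a zero-mean Gaussian whose
#' standard deviation follows triangulation parallax:
#' \code{sigma = min(sigma0 / max(theta, theta_min), sigma_max)} with
#' \code{theta} the widest angle (radians) between the viewing rays across
#' the vertex's longest visible run. A vertex whose rays never diverge
#' (e.g. on the rotation axis under a nadir camera) has its depth
#' unconstrained and receives \code{sigma_max}.
#'
#' @param sigma0 parallax noise constant (mm rad).
#' @param theta_min parallax floor (rad) below which depth is unconstrained.
#' @param sigma_max largest perturbation scale (mm).
#' @param n_min minimum number of consecutive visible frames.
#' @param seed base seed for the perturbation draws.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(sigma0 = 0.05, theta_min = 0.01, sigma_max = 5,
                        n_min = 9L, seed = 1L) {
  if (sigma0 <= 0 || theta_min <= 0 || sigma_max <= 0 || n_min <= 0)
    stop("all noise model parameters must be positive")
  structure(list(sigma0 = sigma0, theta_min = theta_min,
                 sigma_max = sigma_max, n_min = as.integer(n_min),
                 seed = seed),
            class = "noise_model")
}

.cam_index <- function(rig, camera) {
  if (is.character(camera)) camera <- match(camera, rig$ids)
  camera <- as.integer(camera)
  if (is.na(camera) || camera < 1L || camera > length(rig$vza))
    stop("unknown camera")
  camera
}

# camera positions in the (fixed-plant) scene frame, one row per pose:
# rotating the plant by +theta is rotating the camera by -theta
.pose_camera_positions <- function(rig, camera, schedule) {
  p <- rig$positions[.cam_index(rig, camera), ]
  t(vapply(schedule$poses, function(ang) as.vector(rotation_z(-ang) %*% p),
           numeric(3L)))
}

# longest run of TRUE in a cyclic sequence; returns length and start index
.cyclic_run <- function(v) {
  P <- length(v)
  if (all(v)) return(list(len = P, start = 1L))
  if (!any(v)) return(list(len = 0L, start = NA_integer_))
  d <- c(v, v)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & starts <= P
  len <- pmin(r$lengths[ok], P)
  best <- which.max(len)
  list(len = len[best], start = starts[ok][best])
}

#' Per-face visibility over a turntable rotation
#'
#' For one camera, casts a ray from every face centroid to the camera
#' position at each distinct turntable pose. A face is visible when the ray
#' meets the folded face normal within the rig's foreshortening cutoff and
#' no other face blocks the ray. The longest consecutive-visible run is
#' computed on the cyclic pose sequence; a face visible at every pose is
#' credited with the full frame count (the duplicated 0/360-degree endpoint
#' included).
#'
#' @param scene a \code{\link{triangle_mesh}}.
#' @param rig a \code{\link{camera_rig}}.
#' @param camera camera index or id (e.g. \code{"C4"}).
#' @param schedule a \code{\link{turntable_schedule}}.
#' @return a list with \code{visible} (faces x poses logical matrix),
#'   \code{run} (per-face longest consecutive run, in frames) and
#'   \code{camera}.
#' @export
visibility_runs <- function(scene, rig, camera, schedule) {
  if (n_faces(scene) == 0L) stop("empty scene")
  cams <- .pose_camera_positions(rig, camera, schedule)
  vis <- cpp_face_visibility(scene$vertices, scene$faces, cams,
                             cos(rig$max_incidence * pi / 180))
  P <- length(schedule$poses)
  run <- apply(vis, 1L, function(v) .cyclic_run(v)$len)
  if (schedule$n_frames > P) run[run == P] <- schedule$n_frames
  list(visible = vis, run = as.integer(run),
       camera = rig$ids[.cam_index(rig, camera)])
}

# per-vertex visibility: a vertex is seen in a pose when any incident face is
.vertex_visibility <- function(scene, vis) {
  nv <- n_vertices(scene)
  P <- ncol(vis)
  vv <- matrix(FALSE, nv, P)
  F <- scene$faces
  for (p in seq_len(P)) {
    f <- which(vis[, p])
    if (length(f)) vv[unique(as.vector(F[f, , drop = FALSE])), p] <- TRUE
  }
  vv
}

#' Emulate the reconstruction of one per-VZA partial model
#'
#' Applies the consecutive-frame rule and the parallax noise model of a
#' \code{\link{noise_model}} to the exact visibility geometry: a face is
#' reconstructed when each of its vertices stays visible for at least
#' \code{n_min} consecutive frames; every reconstructed vertex is displaced
#' along its mean viewing ray by a seeded Gaussian draw with the
#' parallax-dependent scale. Deterministic for a fixed seed.
#'
#' @inheritParams visibility_runs
#' @param noise a \code{\link{noise_model}}.
#' @param visibility optional precomputed result of
#'   \code{\link{visibility_runs}} for this camera.
#' @return an object of class \code{partial_model}: the detected face subset,
#'   perturbed vertex positions, per-vertex noise scale and per-face longest
#'   runs.
#' @export
reconstruct_single_vza <- function(scene, rig, camera, schedule, noise,
                                   visibility = NULL) {
  ci <- .cam_index(rig, camera)
  if (is.null(visibility))
    visibility <- visibility_runs(scene, rig, camera, schedule)
  vis <- visibility$visible
  P <- length(schedule$poses)
  if (noise$n_min > schedule$n_frames)
    warning("n_min exceeds the number of frames; nothing can be detected")
  vv <- .vertex_visibility(scene, vis)
  vruns <- apply(vv, 1L, .cyclic_run)
  vlen <- vapply(vruns, `[[`, 0L, "len")
  vlen_frames <- vlen
  if (schedule$n_frames > P) vlen_frames[vlen == P] <- schedule$n_frames
  vstart <- vapply(vruns, function(r)
    if (is.na(r$start)) 1L else r$start, 0L)
  vert_ok <- vlen_frames >= noise$n_min
  F <- scene$faces
  detected <- which(vert_ok[F[, 1L]] & vert_ok[F[, 2L]] & vert_ok[F[, 3L]])
  cams <- .pose_camera_positions(rig, camera, schedule)
  nv <- n_vertices(scene)
  sigma <- rep(NA_real_, nv)
  vertices <- scene$vertices
  used <- sort(unique(as.vector(F[detected, , drop = FALSE])))
  if (length(used)) {
    dirs <- matrix(0, length(used), 3L)
    for (k in seq_along(used)) {
      v <- used[k]
      frames <- (vstart[v] + seq_len(vlen[v]) - 2L) %% P + 1L
      U <- cams[frames, , drop = FALSE] -
        matrix(vertices[v, ], length(frames), 3L, byrow = TRUE)
      U <- U / sqrt(rowSums(U * U))
      theta <- if (nrow(U) < 2L) 0 else {
        acos(max(-1, min(1, min(U %*% t(U)))))
      }
      sigma[v] <- min(noise$sigma0 / max(theta, noise$theta_min),
                      noise$sigma_max)
      m <- colMeans(U)
      dirs[k, ] <- m / sqrt(sum(m * m))
    }
    delta <- with_seed(noise$seed + 101L * ci,
                       stats::rnorm(length(used), 0, sigma[used]))
    vertices[used, ] <- vertices[used, ] + dirs * delta
  }
  structure(list(camera = rig$ids[ci], vza = rig$vza[ci],
                 faces = detected,
                 vertices = vertices,
                 sigma = sigma,
                 face_runs = visibility$run,
                 vertex_runs = vlen_frames,
                 visible = vis,
                 scene_faces = scene$faces,
                 scene_vertices = scene$vertices,
                 scene_labels = scene$labels,
                 n_frames = schedule$n_frames),
            class = "partial_model")
}

#' @export
print.partial_model <- function(x, ...) {
  cat("partial_model from", x$camera, sprintf("(VZA %g deg):", x$vza),
      length(x$faces), "of", nrow(x$scene_faces), "faces detected\n")
  s <- x$sigma[!is.na(x$sigma)]
  if (length(s))
    cat(sprintf("noise scale: median %.3f mm, max %.3f mm\n",
                stats::median(s), max(s)))
  invisible(x)
}

#' Convert a model to a plain triangle mesh
#'
#' For partial and merged models the result carries the (perturbed or fused)
#' vertex positions and only the detected faces, with their organ labels.
#'
#' @param x a \code{triangle_mesh}, \code{partial_model} or
#'   \code{merged_model}.
#' @return a \code{\link{triangle_mesh}}.
#' @export
as_triangle_mesh <- function(x) UseMethod("as_triangle_mesh")

#' @export
as_triangle_mesh.triangle_mesh <- function(x) x

#' @export
as_triangle_mesh.partial_model <- function(x) {
  triangle_mesh(x$vertices, x$scene_faces[x$faces, , drop = FALSE],
                labels = if (is.null(x$scene_labels)) NULL
                         else x$scene_labels[x$faces],
                clean = FALSE)
}

#' Overlap-count map
#'
#' Number of images (camera x frame) in which each face is visible, summed
#' over the selected cameras — the overlap map used to judge whether enough
#' consecutive coverage exists for feature matching.
#'
#' @inheritParams visibility_runs
#' @param cameras camera indices or ids.
#' @return integer vector, one count per face, in
#'   \code{[0, length(cameras) * n_frames]}.
#' @export
overlap_map <- function(scene, rig, cameras, schedule) {
  counts <- integer(n_faces(scene))
  for (cam in cameras) {
    v <- visibility_runs(scene, rig, cam, schedule)$visible
    counts <- counts + as.integer(rowSums(v[, schedule$frame_pose,
                                            drop = FALSE]))
  }
  counts
}
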
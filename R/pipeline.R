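.default_config <- function() {
  list(
    seed = 1L,
    plant = list(),           # overrides for plant_spec()
    single_leaf = list(       # the one-leaf scene for VZA selection
      length = 50, width = 34, inclination = 0, height = 30),
    rig = list(n_cameras = 10L, vza_step = 12, range = 1000,
               max_incidence = 70),
    schedule = list(n_frames = 41L, step = 9),
    noise = list(sigma0 = 0.05, theta_min = 0.01, sigma_max = 5,
                 n_min = 9L),
    segmentation = list(threshold = 45, stable_min = 95,
                        unstable_max = 2.5, undetected_max = 2))
}

#' Build and validate a run configuration
#'
#' Merges user settings (an R list or a JSON file) over the documented
#' defaults. Unknown keys are rejected with their field path. Every rig
#' constant (12-degree camera spacing, 41 frames, 1 m range, the
#' 45-degree stability threshold, the 95 / 2.5 / 2 percent selection
#' criteria, the 9-consecutive-frame rule) is an explicit, overridable
#' field.
#'
#' @param config \code{NULL} (defaults), a named list of overrides, or the
#'   path of a JSON file of overrides.
#' @return validated configuration list of class \code{run_config}.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("'config' must be a list or a JSON file path")
  base <- .default_config()
  merge_into <- function(base, user, path = "") {
    for (nm in names(user)) {
      here <- paste0(path, nm)
      if (!nm %in% names(base))
        stop("unknown configuration key: ", here)
      if (is.list(base[[nm]]) && nm != "plant") {
        if (!is.list(user[[nm]]))
          stop("configuration key ", here, " must be a section")
        base[[nm]] <- merge_into(base[[nm]], user[[nm]],
                                 paste0(here, "$"))
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(base, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("configuration key seed must be a single number")
  structure(cfg, class = "run_config")
}

.config_objects <- function(cfg) {
  rig_vza <- cfg$rig$vza_step * (seq_len(cfg$rig$n_cameras) - 1L)
  list(
    rig = camera_rig(n_cameras = cfg$rig$n_cameras, vza = rig_vza,
                     range = cfg$rig$range,
                     max_incidence = cfg$rig$max_incidence),
    schedule = turntable_schedule(cfg$schedule$n_frames, cfg$schedule$step),
    noise = noise_model(cfg$noise$sigma0, cfg$noise$theta_min,
                        cfg$noise$sigma_max, cfg$noise$n_min,
                        seed = cfg$seed))
}

#' Simulate an acquisition and write its artifacts
#'
#' Generates the synthetic plant scene and ground truth, reconstructs one
#' partial model per camera and writes everything to \code{out_dir}:
#' \code{scene.ply} (labeled), \code{ground_truth.csv}, one
#' \code{partial_<camera>.ply} plus a sidecar JSON (noise scales, runs) per
#' camera, and \code{manifest.json} listing every artifact with its MD5
#' checksum. Deterministic for a fixed seed.
#'
#' @param config see \code{\link{run_config}}.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_simulation <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- .config_objects(cfg)
  spec <- do.call(plant_spec, c(cfg$plant, list(seed = cfg$seed)))
  plant <- generate_plant(spec)
  write_mesh(plant$mesh, file.path(out_dir, "scene.ply"))
  write_ground_truth(plant$ground_truth,
                     file.path(out_dir, "ground_truth.csv"))
  files <- c("scene.ply", "ground_truth.csv")
  if (obj$noise$n_min > obj$schedule$n_frames)
    warning("n_min exceeds n_frames: all partial models will be empty")
  for (i in seq_along(obj$rig$vza)) {
    pm <- suppressWarnings(
      reconstruct_single_vza(plant$mesh, obj$rig, i, obj$schedule,
                             obj$noise))
    mesh_file <- sprintf("partial_%s.ply", pm$camera)
    side_file <- sprintf("partial_%s.json", pm$camera)
    if (length(pm$faces) > 0L)
      write_mesh(as_triangle_mesh(pm), file.path(out_dir, mesh_file))
    jsonlite::write_json(
      list(camera = pm$camera, vza = pm$vza,
           n_detected = length(pm$faces),
           faces = pm$faces,
           sigma = round(pm$sigma, 6),
           face_runs = pm$face_runs),
      file.path(out_dir, side_file), auto_unbox = TRUE, na = "null")
    files <- c(files, if (length(pm$faces) > 0L) mesh_file, side_file)
  }
  manifest <- list(seed = cfg$seed,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out_dir, files))),
                     files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full analysis pipeline
#'
#' The end-to-end flow: a single-leaf VZA sweep is segmented per camera and
#' the optimum VZA set selected; the whole-plant scene is reconstructed from
#' the selected cameras by Method 1 (merge per-VZA models) and Method 2
#' (joint model); traits are extracted from both and tabulated against
#' ground truth. Results are written to \code{out_dir} as CSV/JSON when it
#' is given.
#'
#' @param config see \code{\link{run_config}}.
#' @param out_dir optional output directory for the report files.
#' @return a list with the per-camera region table, the optimum VZA
#'   selection, the \code{method_comparison} and the comparison data frame.
#' @export
run_analysis <- function(config = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  obj <- .config_objects(cfg)
  sl <- cfg$single_leaf
  leaf <- generate_leaf(sl$length, sl$width, inclination = sl$inclination,
                        attach = c(-sl$length / 2, 0, sl$height),
                        resolution = 2, label = "L1")
  scene1 <- merge_meshes(list(leaf$mesh, .make_soil(270)))
  rig1 <- camera_rig(n_cameras = cfg$rig$n_cameras,
                     vza = obj$rig$vza, range = cfg$rig$range,
                     center = c(0, 0, sl$height),
                     max_incidence = cfg$rig$max_incidence)
  measured <- leaf$ground_truth$area_cm2 * 100
  reports <- lapply(seq_along(rig1$vza), function(i)
    classify_regions(
      reconstruct_single_vza(scene1, rig1, i, obj$schedule, obj$noise),
      measured_area = measured, organ = "L1",
      threshold = cfg$segmentation$threshold))
  sel <- suppressWarnings(
    select_optimum_vzas(reports,
                        stable_min = cfg$segmentation$stable_min,
                        unstable_max = cfg$segmentation$unstable_max,
                        undetected_max = cfg$segmentation$undetected_max))
  cameras <- if (length(sel$index) >= 2L) sel$index
             else seq_along(rig1$vza)[-1L]
  spec <- do.call(plant_spec, c(cfg$plant, list(seed = cfg$seed)))
  plant <- generate_plant(spec)
  rig2 <- camera_rig(n_cameras = cfg$rig$n_cameras, vza = obj$rig$vza,
                     range = cfg$rig$range,
                     center = c(0, 0, plant$ground_truth$plant_height / 2),
                     max_incidence = cfg$rig$max_incidence)
  cmp <- compare_methods(plant$mesh, plant$ground_truth, rig2, cameras,
                         obj$schedule, obj$noise)
  cmp_df <- as.data.frame(cmp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sel$table,
                     file.path(out_dir, "region_reports.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(cameras = sel$cameras, vza_range = sel$vza_range),
      file.path(out_dir, "optimum_vza.json"), auto_unbox = TRUE)
    utils::write.csv(cmp_df, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$traits$M1$organs,
                     file.path(out_dir, "traits_m1.csv"), row.names = FALSE)
    utils::write.csv(cmp$traits$M2$organs,
                     file.path(out_dir, "traits_m2.csv"), row.names = FALSE)
  }
  list(region_table = sel$table, optimum = sel, comparison = cmp,
       comparison_table = cmp_df)
}
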
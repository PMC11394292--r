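#' Default pipeline configuration
#'
#' Nested configuration driving [run_pipeline()], one section per stage.
#' Unknown keys are rejected so typos fail loudly; the bare default runs the
#' synthetic demo end to end. Sections and keys:
#' `synthetic` (sheep/scene generator settings), `denoise.passthrough`
#' (list of crop boxes, world frame), `denoise.sor` (`k`, `r_sigma`),
#' `denoise.ransac` (`alpha`, `k_iters`), `downsample` (`mode` one of
#' `conditional_voxel`, `voxel`, `off`; `lam`, `radius`, `min_neighbors`),
#' `repair` (`enabled`, `views`, `spacing`, `rim_min_points`, `min_cells`),
#' `register` (`reference_view`, `coarse`, `icp`, `features`),
#' `measure` (`q`), `io` (`out_dir`, `write_stages`), plus the global `seed`
#' and `log_level`.
#'
#' @param overrides named nested list of settings to override.
#' @return the merged configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1,
    log_level = "info",
    io = list(out_dir = NULL, write_stages = FALSE),
    synthetic = list(sheep = list(), scene = list()),
    denoise = list(
      passthrough = list(list(min = c(-1.0, -0.55, -0.05),
                              max = c(1.0, 0.55, 1.1))),
      sor = list(k = 24, r_sigma = 0.6),
      ransac = list(alpha = 0.02, k_iters = 550)),
    downsample = list(mode = "conditional_voxel", lam = 0.01, radius = 0.03,
                      min_neighbors = 16),
    repair = list(enabled = TRUE, views = "front", spacing = NULL,
                  rim_min_points = 6, min_cells = 3),
    register = list(reference_view = "top",
                    coarse = list(v_thresh = 1e-4, t_iters = 1000),
                    icp = list(max_iters = 100, eps = 1e-7,
                               max_corr_dist = 0.02, symmetric = TRUE,
                               trust_rot_deg = 1.5, trust_trans = 0.015),
                    features = list(radius = 0.05)),
    measure = list(q = 0.002, equalize_lam = 0.01))
  merge_config(defaults, overrides, path = "")
}

merge_config <- function(defaults, overrides, path = "") {
  if (!is.list(overrides)) stop("config section '", path, "' must be a list")
  extra <- setdiff(names(overrides), names(defaults))
  # list-valued leaves (crop boxes, repair views, scene params) are free-form
  free <- c("passthrough", "sheep", "scene", "views")
  if (length(extra) > 0 && !basename(path) %in% free)
    stop("unknown config key(s) under '", path, "': ",
         paste(extra, collapse = ", "))
  out <- defaults
  for (nm in names(overrides)) {
    if (nm %in% names(defaults) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])) && basename(path) != "passthrough" &&
        !nm %in% free) {
      out[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                paste0(path, "/", nm))
    } else {
      out[[nm]] <- overrides[[nm]]
    }
  }
  structure(out, class = if (path == "") "pipeline_config" else NULL)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return the merged configuration.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

plog <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(...)
}

#' Run the full reconstruction pipeline
#'
#' Executes the measurement chain in capture order: simulate (or accept) the
#' three camera views, bring each into the world frame with the calibrated
#' extrinsics, preprocess each view (passthrough crop, statistical outlier
#' removal, RANSAC ground removal, conditional voxel downsampling, and
#' spline hole repair on the occluded views), register the views
#' (coarse-to-fine onto the reference view), normalize the pose (gravity-
#' referenced yaw normalization, see [normalize_upright()]) and measure body
#' length on the density-equalized cloud.
#'
#' @param config a [pipeline_config()].
#' @param scene optional pre-built [make_scene()] result; by default a scene
#'   is generated from `config$synthetic` and `config$seed`.
#' @return a `pipeline_report` list: per-stage point counts per view,
#'   per-view transforms, `body_length_cm`, `truth` (with
#'   `error_pct` against the synthetic ground truth), the yaw correction
#'   applied by the normalization, timings in seconds, and the seed.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL) {
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed
  if (is.null(scene)) {
    sp <- do.call(sheep_params, utils::modifyList(
      config$synthetic$sheep, list(seed = derive_seed(seed, "sheep"))))
    sc <- do.call(scene_params, config$synthetic$scene)
    scene <- make_scene(sp, sc, seed = derive_seed(seed, "scene"))
  }
  counts <- list()
  views <- list()
  sensor_views <- list()
  timings <- list()
  for (nm in names(scene$views)) {
    v <- scene$views[[nm]]
    counts[[nm]] <- c(raw = n_points(v))
    # calibrated extrinsics bring the view into the world frame
    v <- transform_cloud(v, scene$calib[[nm]], frame = "world")
    for (box in config$denoise$passthrough)
      v <- passthrough_box(v, bbox(box$min, box$max))
    counts[[nm]]["passthrough"] <- n_points(v)
    sor <- statistical_outlier_removal(v, k = config$denoise$sor$k,
                                       r_sigma = config$denoise$sor$r_sigma)
    v <- sor$cloud
    counts[[nm]]["sor"] <- n_points(v)
    v <- remove_ground(v, alpha = config$denoise$ransac$alpha,
                       k_iters = config$denoise$ransac$k_iters,
                       seed = derive_seed(seed, paste0("ransac_", nm)))
    counts[[nm]]["ground_removed"] <- n_points(v)
    ds <- config$downsample
    v <- switch(ds$mode,
      off = v,
      voxel = voxel_centroid_downsample(v, ds$lam),
      conditional_voxel = conditional_voxel_filter(v, ds$lam, ds$radius,
                                                   ds$min_neighbors),
      stop("unknown downsample mode '", ds$mode, "'"))
    counts[[nm]]["downsample"] <- n_points(v)
    sensor_views[[nm]] <- v
    if (isTRUE(config$repair$enabled) && nm %in% config$repair$views) {
      # occlusion holes live in the image plane: project along the view axis
      v <- repair_cloud(v, min_cells = config$repair$min_cells,
                        rim_min_points = config$repair$rim_min_points,
                        spacing = config$repair$spacing,
                        basis = scene$calib[[nm]]$R)
    }
    counts[[nm]]["repair"] <- n_points(v)
    views[[nm]] <- v
    plog(config, sprintf("view %-6s %s", nm,
                         paste(names(counts[[nm]]), counts[[nm]],
                               sep = "=", collapse = " ")))
  }
  timings$preprocess <- proc.time()[["elapsed"]] - t0
  t1 <- proc.time()[["elapsed"]]
  # registration, like measurement, runs on sensor evidence only; the
  # per-view transforms are then applied to the repaired clouds
  reg <- register_views(
    sensor_views,
    init = list(side = rt_identity(), front = rt_identity()),
    coarse_params = c(config$register$coarse,
                      list(radius = config$register$features$radius,
                           seed = derive_seed(seed, "coarse"))),
    icp_params = config$register$icp)
  merged_views <- list()
  for (nm in names(views)) {
    mv <- transform_cloud(views[[nm]], reg$transforms[[nm]], frame = "world")
    mv$attrs$view_id <- rep(match(nm, names(views)), n_points(mv))
    merged_views[[nm]] <- mv
  }
  merged <- cloud_bind(merged_views)
  timings$register <- proc.time()[["elapsed"]] - t1
  t2 <- proc.time()[["elapsed"]]
  # interpolated fill points complete the reconstruction but are not
  # measurement evidence: extremal statistics use sensor-derived points only
  sensor_only <- if (!is.null(merged$attrs$repaired)) {
    cloud_subset(merged, is.na(merged$attrs$repaired) |
                           merged$attrs$repaired == 0)
  } else merged
  norm <- normalize_upright(sensor_only, lam = config$measure$equalize_lam)
  len_cm <- body_length(norm$equalized, q = config$measure$q)
  timings$measure <- proc.time()[["elapsed"]] - t2
  truth <- NULL
  if (!is.null(scene$truth)) {
    truth_cm <- 100 * scene$truth$body_length
    truth <- list(body_length_cm = truth_cm,
                  error_pct = relative_error(truth_cm, len_cm),
                  yaw_deg = scene$truth$yaw_deg,
                  pitch_deg = scene$truth$pitch_deg)
  }
  report <- structure(list(
    counts = counts,
    merged_points = n_points(merged),
    transforms = reg$transforms,
    yaw_correction_deg = norm$yaw_deg,
    body_length_cm = len_cm,
    truth = truth,
    timings = timings,
    seed = seed), class = "pipeline_report")
  if (!is.null(config$io$out_dir)) {
    dir.create(config$io$out_dir, recursive = TRUE, showWarnings = FALSE)
    # labels are character attrs and have no PLY representation
    suppressWarnings(write_cloud(merged,
                                 file.path(config$io$out_dir, "merged.ply")))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$io$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  list(counts = report$counts,
       merged_points = report$merged_points,
       transforms = lapply(report$transforms, function(rt)
         list(rotation = rt$R, translation = rt$T)),
       yaw_correction_deg = report$yaw_correction_deg,
       body_length_cm = report$body_length_cm,
       truth = report$truth,
       timings = report$timings,
       seed = report$seed)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-6s %s\n", nm,
                paste(names(x$counts[[nm]]), x$counts[[nm]],
                      sep = "=", collapse = " ")))
  cat(sprintf("  merged: %d points\n", x$merged_points))
  cat(sprintf("  body length: %.2f cm", x$body_length_cm))
  if (!is.null(x$truth))
    cat(sprintf(" (truth %.2f cm, error %.2f%%)",
                x$truth$body_length_cm, x$truth$error_pct))
  cat("\n")
  invisible(x)
}
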
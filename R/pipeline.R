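default_config <- function() {
  list(
    seed = 1,
    verbosity = 1,
    cbct = list(
      threshold_hu = 1200,          # intensity threshold of the classical slice segmenter
      min_component_voxels = 30,    # smallest slice component kept
      arch_points = 400,            # arch samples C
      band_halfwidth_mm = 8,        # panoramic half-thickness w
      pano_min_pixels = 40,         # smallest panoramic component kept
      subvoxel_boundary = TRUE,     # iso-level refinement of boundary voxels
      roi = NULL,                   # list(min=, max=) world-mm crop, or NULL
      mip_z_range = NULL,           # 0-based z range for the axial projection
      arch_threshold = NULL,        # NULL = Otsu
      min_foreground_fraction = 1e-4
    ),
    ios = list(
      k = 15,                       # KNN votes
      max_dist = 0.3,               # embedded HSV neighbourhood radius
      min_cluster = 30,             # smallest teeth cluster kept
      cluster_radius = 1.0          # Euclidean clustering radius, mm
    ),
    register = list(
      voxel_size = 0.5,             # down-sampling voxel, mm, both clouds
      normal_k = 30,                # normal-estimation neighbourhood
      fpfh_radius = 2.5,            # FPFH support radius, mm
      ransac_max_iter = 1e5,
      ransac_min_iter = 20000,      # floor so a competing pose basin is sampled
      ransac_confidence = 0.999,
      edge_similarity = 0.9,        # pairwise edge-length ratio check
      inlier_factor = 2,            # RANSAC inlier distance = factor * voxel
      min_fitness = 0.2,            # required coarse match rate
      score_subset = 2000,          # hypothesis-scoring subsample
      max_surface_variation = 0.15, # descriptor stage keeps surface-like points
      icp_max_corr = 1.5,           # ICP correspondence radius, mm
      icp_max_iter = 100,
      icp_tol = 1e-6,
      icp_refine = 2                # halved-radius refinement re-runs
    ),
    validate = list(
      n_slices = 20,                # coronal slabs for Bland-Altman
      alpha = 1.0,                  # alpha-shape radius, mm
      error_max_scale = 1.0,        # color-map red point, mm
      hist_bin_width = 0.05
    )
  )
}

#' Pipeline configuration
#'
#' Builds the resolved configuration for the full pipeline: every tunable
#' of the segmentation, classification, registration and validation
#' stages, grouped by stage, plus the RNG seed. Unknown keys are rejected;
#' missing keys are filled from the documented defaults. The resolved
#' configuration is echoed into every report the pipeline writes.
#'
#' @param ... Overrides, either as nested lists (`cbct = list(...)`) or
#'   top-level keys (`seed = 7`).
#' @param file Optional YAML file of overrides, merged before `...`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- default_config()
  apply_over <- function(cfg, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(cfg))
        stop("unknown config key: ", path, nm)
      if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]])) &&
          !nm %in% c("roi", "mip_z_range")) {
        if (!is.list(over[[nm]]))
          stop("config key ", path, nm, " must be a list")
        cfg[[nm]] <- apply_over(cfg[[nm]], over[[nm]],
                                paste0(path, nm, "$"))
      } else cfg[[nm]] <- over[[nm]]
    }
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- apply_over(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

log_msg <- function(config, stage, ...) {
  if (isTRUE(config$verbosity >= 1))
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full CBCT / intraoral-scan registration pipeline
#'
#' Executes segment-cbct, segment-ios, per-jaw registration (upper IOS to
#' upper CBCT jaw, lower to lower) and validation, writing transforms
#' (`T_upper.txt`, `T_lower.txt`), JSON reports carrying the resolved
#' configuration and seed, error-map PLYs and a log into `out_dir`.
#'
#' @param cbct_path CBCT volume path (NIfTI/NRRD/DICOM directory).
#' @param ios_upper_path,ios_lower_path Colored IOS surface paths.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param slice_segmenter,pano_segmenter Optional segmenter overrides.
#' @param train Optional [color_training_set()].
#' @return Invisibly, a list with per-jaw `registration` and `validation`
#'   plus the `jaw_split`; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(cbct_path, ios_upper_path, ios_lower_path,
                         config = pipeline_config(), out_dir = "dentreg_run",
                         slice_segmenter = NULL, pano_segmenter = NULL,
                         train = NULL) {
  for (p in c(cbct_path, ios_upper_path, ios_lower_path))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- list()
  volume <- read_volume(cbct_path)
  ios <- list(upper = read_surface(ios_upper_path, require_color = TRUE),
              lower = read_surface(ios_lower_path, require_color = TRUE))
  log_msg(config, stage, "volume ", paste(dim(volume$intensities),
                                          collapse = "x"),
          "; IOS upper ", n_points(ios$upper), " pts, lower ",
          n_points(ios$lower), " pts")

  stage <- "segment-cbct"
  seg <- segment_cbct(volume, config, slice_segmenter, pano_segmenter)
  js <- seg$jaw_split
  log_msg(config, stage, nrow(js$upper_points), " upper voxels, ",
          nrow(js$lower_points), " lower voxels")

  stage <- "segment-ios"
  teeth <- lapply(ios, segment_ios, config = config, train = train)
  log_msg(config, stage, "teeth points: upper ", n_points(teeth$upper),
          ", lower ", n_points(teeth$lower))

  out <- list(jaw_split = js, config = config)
  for (jaw in c("upper", "lower")) {
    stage <- paste0("register-", jaw)
    cb <- if (jaw == "upper") js$upper_points else js$lower_points
    if (nrow(cb) == 0) stop("no CBCT ", jaw, " jaw points segmented")
    reg <- register_jaw(teeth[[jaw]], cb, config)
    log_msg(config, stage, sprintf("fitness %.3f, inlier RMSE %.3f mm",
                                   reg$fitness, reg$inlier_rmse))
    stage <- paste0("validate-", jaw)
    val <- validate_registration(reg, teeth[[jaw]], cb, config)
    write_transform(reg$transform,
                    file.path(out_dir, paste0("T_", jaw, ".txt")))
    write_surface(val$error_map$surface,
                  file.path(out_dir, paste0("errormap_", jaw, ".ply")))
    ba <- val$bland_altman
    utils::write.csv(data.frame(mean_area = ba$means,
                                difference = ba$differences),
                     file.path(out_dir, paste0("bland_altman_", jaw, ".csv")),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, paste0("bland_altman_", jaw, ".png")),
                   width = 640, height = 480)
    plot(ba, main = paste("Coronal section areas,", jaw, "jaw"))
    grDevices::dev.off()
    report <- list(
      jaw = jaw,
      seed = config$seed,
      config = unclass(config),
      fitness = reg$fitness, inlier_rmse = reg$inlier_rmse,
      fi_ratio = reg$fi_ratio, fi_threshold = val$fi_threshold,
      mean_distance_mm = val$distance_report$mean,
      sd_distance_mm = val$distance_report$sd,
      chamfer_mm = val$chamfer$symmetric,
      hausdorff_mm = val$hausdorff$symmetric,
      bland_altman = list(bias = val$bland_altman$bias,
                          limits = unname(val$bland_altman$limits),
                          fraction_within = val$bland_altman$fraction_within))
    jsonlite::write_json(report, file.path(out_dir,
                                           paste0("report_", jaw, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    out[[jaw]] <- list(registration = reg, validation = val)
  }
  log_msg(config, "done", "artifacts in ", out_dir)
  invisible(out)
}
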
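#' @include AllClasses.R
NULL

.pipelineConfigKeys <- c(
  "scene_dir", "label_volume", "voxel_size_nm", "organelle_names",
  "thresholds_nm", "smoothing_iterations", "smoothing_alpha",
  "smoothing_beta", "wrinkle_sd_factor", "wrinkle_min_faces",
  "wrinkle_surface", "ratio_pairs", "proximity_pairs", "output_dir",
  "seed", "log_level")

#' Validate a pipeline configuration
#'
#' Checks the configuration (a named list, or a JSON/YAML file path) against
#' the known schema before any computation: unknown keys are rejected,
#' exactly one input (\code{scene_dir} or \code{label_volume}) is required,
#' and numeric fields are range-checked. Defaults are filled in.
#'
#' @param config named list, or path to a \code{.json}/\code{.yaml} file.
#' @return the validated, default-completed configuration list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::fromJSON(config, simplifyVector = TRUE),
      yaml = , yml = {
        if (!requireNamespace("yaml", quietly = TRUE))
          stop("the yaml package is required for YAML configs")
        yaml::read_yaml(config)
      },
      stop("config file must be .json or .yaml"))
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  unknown <- setdiff(names(config), .pipelineConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$scene_dir) && is.null(config$label_volume))
    stop("config needs an input: scene_dir or label_volume")
  if (!is.null(config$scene_dir) && !is.null(config$label_volume))
    stop("config must set only one of scene_dir / label_volume")
  defaults <- list(thresholds_nm = c(100, 24), smoothing_iterations = 3L,
                   smoothing_alpha = 0, smoothing_beta = 0.5,
                   wrinkle_sd_factor = 1, wrinkle_min_faces = 10L,
                   wrinkle_surface = NA_character_,
                   ratio_pairs = list(c("chloroplast", "mitochondrion")),
                   proximity_pairs = list(
                     c("chloroplast", "mitochondrion"),
                     c("mitochondrion", "chloroplast"),
                     c("chloroplast", "LD"),
                     c("mitochondrion", "LD"),
                     c("mitochondrion", "starch")),
                   output_dir = "cystmorph_out", seed = 1L,
                   log_level = "info")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (any(config$thresholds_nm <= 0)) stop("thresholds_nm must be positive")
  if (config$smoothing_iterations < 0) stop("smoothing_iterations must be >= 0")
  if (!is.null(config$label_volume) && is.null(config$voxel_size_nm))
    stop("voxel_size_nm is required with a label_volume input")
  # normalise pair lists coming from JSON matrices
  fixPairs <- function(p) {
    if (is.matrix(p)) p <- split(p, seq_len(nrow(p)))
    lapply(p, as.character)
  }
  config$ratio_pairs <- fixPairs(config$ratio_pairs)
  config$proximity_pairs <- fixPairs(config$proximity_pairs)
  config
}

.logMsg <- function(level, cfg, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (lv[[level]] >= lv[[cfg$log_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full morphometry pipeline
#'
#' Executes the analysis stages in order: load the scene (from a scene
#' directory or by isosurface extraction from a label volume), validate the
#' meshes, compute metrics/ratios/proximities into a morphometry report,
#' optionally quantify wrinkles on a chosen surface (HC smoothing for the
#' area gain plus curvature-based ridge statistics), and serialize
#' everything (JSON report, CSV tables, manifest with md5 checksums and the
#' config hash) into \code{output_dir}.
#'
#' @param config named list or config-file path; see [pipelineConfig()].
#' @return the [MorphometryReport-class], invisibly; artifacts on disk.
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  .logMsg("info", cfg, "stage load")
  scene <- tryCatch({
    if (!is.null(cfg$scene_dir)) readScene(cfg$scene_dir)
    else {
      vol <- readLabelVolume(cfg$label_volume, voxelSize = cfg$voxel_size_nm,
                             labelMap = unlist(cfg$organelle_names))
      labelsToMeshes(vol)
    }
  }, error = function(e) stop("stage 'load' failed: ", conditionMessage(e)))

  .logMsg("info", cfg, "stage validate (", length(scene@meshes), " meshes)")
  for (nm in names(scene@meshes)) {
    rep <- validateMesh(scene@meshes[[nm]])
    if (!rep@watertight)
      warning("mesh '", nm, "' is not watertight; metric results flagged ",
              "approximate")
  }

  .logMsg("info", cfg, "stage report")
  report <- assembleReport(scene, ratioPairs = cfg$ratio_pairs,
                           proximityPairs = cfg$proximity_pairs,
                           thresholds = cfg$thresholds_nm, seed = cfg$seed)

  wrinkleOut <- NULL
  wsurf <- cfg$wrinkle_surface
  if (!is.na(wsurf)) {
    .logMsg("info", cfg, "stage wrinkles on ", wsurf)
    mesh <- if (wsurf == "cell") scene@cellBoundary else scene@meshes[[wsurf]]
    if (is.null(mesh)) stop("stage 'wrinkles' failed: surface '", wsurf,
                            "' not in scene")
    sm <- hcLaplacianSmooth(mesh, SmoothingParams(cfg$smoothing_iterations,
                                                  cfg$smoothing_alpha,
                                                  cfg$smoothing_beta))
    ws <- detectWrinkles(mesh, curvatureSdFactor = cfg$wrinkle_sd_factor,
                         minComponentFaces = cfg$wrinkle_min_faces)
    wrinkleOut <- list(area_gain_percent = wrinkleAreaGain(mesh, sm),
                      stats = ws)
    wrinkleStatsJSON(ws, file.path(cfg$output_dir, "wrinkles.json"))
  }

  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null")
  cfgTmp <- file.path(cfg$output_dir, "config.json")
  writeLines(cfgJson, cfgTmp)
  # the hash covers the analysis parameters, not run-local output locations
  hashCfg <- cfg[setdiff(names(cfg), c("output_dir", "log_level"))]
  hashTmp <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(hashCfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), hashTmp)
  report@provenance$config_md5 <- unname(tools::md5sum(hashTmp))
  unlink(hashTmp)
  if (!is.null(wrinkleOut))
    report@provenance$wrinkle_area_gain_percent <- wrinkleOut$area_gain_percent

  .logMsg("info", cfg, "stage serialize")
  reportJSON(report, file.path(cfg$output_dir, "report.json"),
             csvPrefix = file.path(cfg$output_dir, "report"))

  files <- setdiff(list.files(cfg$output_dir, full.names = TRUE),
                   file.path(cfg$output_dir, "manifest.csv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(cfg$output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(report)
}
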
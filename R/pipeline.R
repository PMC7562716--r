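# Declarative pipeline wiring: mask -> patch -> stain-normalize -> predict ->
# heatmap -> featurize -> classify, with resumable per-stage outputs, a
# resolved-config dump, structured JSON-line logs and one global seed fanned
# out to per-stage seeds.

pipeline_defaults <- function() {
  list(
    out_dir = "slideheat-out",
    seed = 1,
    slides = NULL,            # list of slideheat_slide, or paths, or NULL
    reference = NULL,         # stain profile / reference image path / NULL
    patch_classifier = NULL,  # slideheat_patch_classifier or .rds path
    slide_classifier = NULL,  # slideheat_slide_classifier or NULL
    stages = list(mask = TRUE, normalize = FALSE, predict = TRUE,
                  heatmap = TRUE, featurize = TRUE, classify = FALSE),
    mask_params = list(downsample = 32, close_radius = 4,
                       min_area_fraction = 0.005),
    patch_params = list(scales = 1024, stride_fraction = 1, out_side = 299,
                        min_tissue_fraction = 0.25),
    stain_params = list(beta = 0.15, alpha = 0.01),
    heatmap_params = list(cell_size = 1024)
  )
}

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; every run writes the resolved configuration
#' next to its outputs so a run can be reproduced from the output directory
#' alone.
#'
#' @param ... Overrides of the default configuration (see
#'   `pipeline_defaults` in the source for the full key set: `out_dir`,
#'   `seed`, `slides`, `reference`, `patch_classifier`, `slide_classifier`,
#'   `stages`, `mask_params`, `patch_params`, `stain_params`,
#'   `heatmap_params`).
#' @return A `slideheat_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  for (nested in c("stages", "mask_params", "patch_params", "stain_params",
                   "heatmap_params")) {
    bad <- setdiff(names(cfg[[nested]]), names(defaults[[nested]]))
    if (length(bad))
      stopf("unknown key(s) in %s: %s", nested, paste(bad, collapse = ", "))
  }
  structure(cfg, class = "slideheat_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Only the serializable scalar parameters are written (objects such as
#' in-memory slides or classifiers are replaced by their recorded paths).
#'
#' @param config A `slideheat_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  for (k in c("slides", "reference", "patch_classifier", "slide_classifier"))
    if (!is.null(ser[[k]]) && !is.character(ser[[k]]))
      ser[[k]] <- sprintf("<in-memory %s>", k)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_line <- function(con, stage, slide = NULL, ...) {
  entry <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage)
  if (!is.null(slide)) entry$slide <- slide
  extra <- list(...)
  entry[names(extra)] <- extra
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

resolve_slides <- function(cfg) {
  if (is.null(cfg$slides)) stopf("config$slides is empty: nothing to process")
  lapply(cfg$slides, function(s) {
    if (inherits(s, "slideheat_slide")) s else read_slide(s)
  })
}

#' Run the slide-analysis pipeline
#'
#' Executes the enabled stages in order (mask, normalize, predict, heatmap,
#' featurize, classify) for every slide in the configuration, writing one
#' heatmap (16-bit TIFF + JSON sidecar) and one 44-feature row per slide, a
#' features CSV, optional slide-level predictions, the resolved config, a
#' JSON-line log and a checksum manifest into `out_dir`. A disabled stage
#' whose output is required downstream raises an error naming the stage to
#' run.
#'
#' @param config A `slideheat_config`.
#' @return Invisibly, a list with `features` (data frame), `heatmaps`,
#'   `predictions` (or NULL), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "slideheat_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "pipeline.log.jsonl"), open = "wt")
  on.exit(close(logf))
  slides <- resolve_slides(cfg)
  st <- cfg$stages
  classifier <- cfg$patch_classifier
  if (is.character(classifier)) classifier <- load_patch_classifier(classifier)
  if (isTRUE(st$predict) && is.null(classifier))
    stopf("stage 'predict' needs a patch classifier: set config$patch_classifier")
  reference <- cfg$reference
  if (isTRUE(st$normalize)) {
    if (is.null(reference)) stopf("stage 'normalize' needs config$reference")
    if (is.character(reference)) reference <- read_slide(reference)$data
    if (!inherits(reference, "slideheat_stain_profile"))
      reference <- estimate_stain_matrix(reference, cfg$stain_params$beta,
                                         cfg$stain_params$alpha,
                                         source = "pipeline-reference")
  }
  heatmaps <- list()
  feature_rows <- list()
  for (slide in slides) {
    sid <- slide$id
    hm_path <- file.path(cfg$out_dir, paste0(sid, "_heatmap.tif"))
    if (!isTRUE(st$mask))
      stopf("stage 'mask' is disabled but required; enable stages$mask")
    mp <- cfg$mask_params
    thumb <- slide_thumbnail(slide, mp$downsample)
    mask <- compute_tissue_mask(thumb, mp$downsample, mp$close_radius,
                                mp$min_area_fraction)
    log_line(logf, "mask", sid, threshold = mask$threshold,
             tissue_fraction = mean(mask$mask))
    if (isTRUE(st$heatmap)) {
      if (!isTRUE(st$predict))
        stopf("stage 'heatmap' needs patch predictions; enable stages$predict")
      pp <- cfg$patch_params
      patches <- extract_patches(slide, mask, scales = pp$scales,
                                 stride_fraction = pp$stride_fraction,
                                 out_side = pp$out_side,
                                 min_tissue_fraction = pp$min_tissue_fraction)
      rasters <- lapply(patches, `[[`, "raster")
      if (isTRUE(st$normalize) && length(rasters))
        rasters <- lapply(rasters, normalize_to_reference, reference = reference,
                          beta = cfg$stain_params$beta, alpha = cfg$stain_params$alpha)
      preds <- if (length(rasters)) {
        probs <- predict(classifier, rasters)
        data.frame(x = vapply(patches, `[[`, 0, "x"),
                   y = vapply(patches, `[[`, 0, "y"),
                   w = vapply(patches, `[[`, 0, "scale"),
                   h = vapply(patches, `[[`, 0, "scale"),
                   prob = malignancy_probability(probs))
      } else data.frame(x = numeric(), y = numeric(), w = numeric(),
                        h = numeric(), prob = numeric())
      hm <- suppressWarnings(
        assemble_heatmap(preds, c(slide$width, slide$height),
                         cell_size = cfg$heatmap_params$cell_size,
                         tissue = mask, slide_id = sid))
      write_heatmap(hm, hm_path)
      heatmaps[[sid]] <- hm
      log_line(logf, "heatmap", sid, n_patches = length(patches))
    } else if (file.exists(hm_path)) {
      heatmaps[[sid]] <- read_heatmap(hm_path)  # resume from a prior run
      log_line(logf, "heatmap", sid, resumed = TRUE)
    }
    if (isTRUE(st$featurize)) {
      if (is.null(heatmaps[[sid]]))
        stopf("stage 'featurize' needs a heatmap for '%s'; enable stages$heatmap or provide %s",
              sid, hm_path)
      feature_rows[[sid]] <- unclass(extract_feature_vector(heatmaps[[sid]]))
      log_line(logf, "featurize", sid)
    }
  }
  features <- NULL
  predictions <- NULL
  if (length(feature_rows)) {
    features <- data.frame(slide = names(feature_rows),
                           do.call(rbind, feature_rows), check.names = FALSE,
                           row.names = NULL)
    utils::write.csv(features, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
  }
  if (isTRUE(st$classify)) {
    if (is.null(cfg$slide_classifier))
      stopf("stage 'classify' needs config$slide_classifier")
    if (is.null(features))
      stopf("stage 'classify' needs features; enable stages$featurize")
    res <- classify_slide(cfg$slide_classifier,
                          as.matrix(features[, feature_names_44()]))
    predictions <- data.frame(slide = features$slide, label = res$label,
                              res$probabilities, check.names = FALSE)
    utils::write.csv(predictions, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    log_line(logf, "classify", n_slides = nrow(predictions))
  }
  write_pipeline_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  arts <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                  file.path(cfg$out_dir, c("manifest.csv", "pipeline.log.jsonl")))
  manifest <- data.frame(file = basename(arts), md5 = unname(tools::md5sum(arts)))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_line(logf, "done", n_slides = length(slides))
  invisible(list(features = features, heatmaps = heatmaps,
                 predictions = predictions, out_dir = cfg$out_dir))
}
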
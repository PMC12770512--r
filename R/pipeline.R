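#' Pipeline run configuration
#'
#' Nests the per-stage configurations and the stage list; one global seed
#' fans out deterministically to every stage.
#'
#' @param out_dir Root output directory of the run.
#' @param stages Stages to execute, in canonical order: `generate`,
#'   `preprocess`, `features`, `lighten`, `split`, `kfold`, `train`,
#'   `evaluate`.
#' @param synth A [synth_config()].
#' @param feature A [feature_config()].
#' @param split A [split_config()].
#' @param augment An [augment_config()] or `NULL`.
#' @param model A [model_config()].
#' @param clahe_clip,clahe_tiles CLAHE parameters for the preprocess stage.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("generate", "preprocess", "features",
                                       "lighten", "split", "kfold", "train",
                                       "evaluate"),
                            synth = synth_config(),
                            feature = feature_config(),
                            split = split_config(),
                            augment = augment_config(),
                            model = desk_model_config(),
                            clahe_clip = 2, clahe_tiles = c(8, 8),
                            seed = 1) {
  all_stages <- c("generate", "preprocess", "features", "lighten", "split",
                  "kfold", "train", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    abort_config(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  seed <- as.integer(seed)
  synth$seed <- derive_seed(seed, 1L)
  split$seed <- derive_seed(seed, 2L)
  model$seed <- derive_seed(seed, 3L)
  structure(list(out_dir = out_dir,
                 stages = all_stages[all_stages %in% stages],
                 synth = synth, feature = feature, split = split,
                 augment = augment, model = model,
                 clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
                 seed = seed),
            class = "pipeline_config")
}

stage_dir <- function(config, stage) {
  switch(stage,
         generate = file.path(config$out_dir, "raw"),
         preprocess = file.path(config$out_dir, "denoised"),
         features = file.path(config$out_dir, "features"),
         lighten = file.path(config$out_dir, "final2"),
         config$out_dir)
}

require_stage_outputs <- function(config, stage, needed_by) {
  d <- stage_dir(config, stage)
  if (!dir.exists(d) || length(list.files(d, pattern = "\\.png$")) == 0L) {
    abort_dependency(sprintf("stage '%s' requires outputs of stage '%s' (missing: %s)",
                             needed_by, stage, d))
  }
  d
}

file_report <- function(dir, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  list(n_files = length(files),
       checksum = unname(tools::md5sum(files)))
}

# map a raw image path to its processed counterpart
derived_path <- function(path, dir, suffix = "") {
  base <- sub("\\.png$", "", basename(path))
  file.path(dir, paste0(base, suffix, ".png"))
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in canonical order: synthetic generation,
#' enhancement (grayscale/resize/CLAHE/median; outputs carry a `_denoised`
#' suffix), feature processing, midtone lightening (written to a `final2`
#' directory), sealing + hold-out split, k-fold assignment, training and
#' evaluation. Every stage is a pure function of its inputs and
#' configuration, so re-running a stage overwrites its outputs identically.
#'
#' @param config A [pipeline_config()].
#' @return A run report (list of class `pipeline_report`): per-stage file
#'   counts, checksums, timings, and stage-specific results (thresholds,
#'   metrics, history). Also written to `run_report.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must be a pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())

  for (stage in config$stages) {
    t0 <- Sys.time()
    res <- switch(stage,
      generate = stage_generate(config),
      preprocess = stage_preprocess(config),
      features = stage_features(config),
      lighten = stage_lighten(config),
      split = stage_split(config),
      kfold = stage_kfold(config),
      train = stage_train(config),
      evaluate = stage_evaluate(config))
    res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    report$stages[[stage]] <- res
  }
  class(report) <- "pipeline_report"
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

stage_generate <- function(config) {
  dir <- stage_dir(config, "generate")
  manifest <- generate_dataset(config$synth, dir)
  c(list(stage = "generate", manifest = file.path(dir, "manifest.csv")),
    file_report(dir))
}

stage_preprocess <- function(config) {
  raw_dir <- require_stage_outputs(config, "generate", "preprocess")
  manifest <- read_manifest(file.path(raw_dir, "manifest.csv"))
  out_dir <- stage_dir(config, "preprocess")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in manifest$path) {
    img <- preprocess_image(read_gray_png(p),
                            target = config$synth$image_size,
                            clip_limit = config$clahe_clip,
                            tile_grid = config$clahe_tiles)
    write_gray_png(img, derived_path(p, out_dir, "_denoised"))
  }
  c(list(stage = "preprocess"), file_report(out_dir))
}

stage_features <- function(config) {
  den_dir <- require_stage_outputs(config, "preprocess", "features")
  raw_dir <- stage_dir(config, "generate")
  out_dir <- stage_dir(config, "features")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(den_dir, pattern = "_denoised\\.png$", full.names = TRUE))
  thresholds <- numeric(length(files))
  qrows <- vector("list", length(files))
  for (i in seq_along(files)) {
    enhanced <- read_gray_png(files[i])
    feat <- extract_features(enhanced, config$feature)
    thresholds[i] <- feat$otsu$threshold
    raw_path <- file.path(raw_dir, sub("_denoised", "", basename(files[i])))
    if (file.exists(raw_path)) {
      before <- read_gray_png(raw_path)
      qrows[[i]] <- quality_metrics(before, feat$premapped, feat$foreground,
                                    feat$dark_mask)
    }
    write_gray_png(feat$image, file.path(out_dir, sub("_denoised", "", basename(files[i]))))
  }
  qm <- dplyr::bind_rows(qrows)
  qsummary <- if (nrow(qm) > 0L) {
    dplyr::summarise(
      dplyr::group_by(qm, .data$metric),
      mean_before = mean(.data$before, na.rm = TRUE),
      mean_after = mean(.data$after, na.rm = TRUE),
      mean_rel_change = mean(.data$rel_change, na.rm = TRUE),
      frac_improved = mean(.data$rel_change > 0, na.rm = TRUE))
  } else NULL
  res <- c(list(stage = "features",
                otsu_mean = mean(thresholds), otsu_sd = stats::sd(thresholds),
                quality = qsummary),
           file_report(out_dir))
  jsonlite::write_json(res[c("otsu_mean", "otsu_sd", "quality")],
                       file.path(out_dir, "quality_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res
}

stage_lighten <- function(config) {
  feat_dir <- require_stage_outputs(config, "features", "lighten")
  out_dir <- stage_dir(config, "lighten")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in sort(list.files(feat_dir, pattern = "\\.png$", full.names = TRUE))) {
    write_gray_png(midtone_lighten(read_gray_png(p), config$feature),
                   file.path(out_dir, basename(p)))
  }
  c(list(stage = "lighten"), file_report(out_dir))
}

pipeline_manifest_path <- function(config) file.path(config$out_dir, "manifest.csv")

stage_split <- function(config) {
  raw_dir <- require_stage_outputs(config, "generate", "split")
  manifest <- read_manifest(file.path(raw_dir, "manifest.csv"))
  sealed <- seal_classes(manifest, config$split)
  sealed <- holdout_split(sealed, config$split)
  write_manifest(sealed, pipeline_manifest_path(config))
  list(stage = "split",
       n_train = sum(sealed$split == "train"),
       n_test = sum(sealed$split == "test"))
}

stage_kfold <- function(config) {
  raw_dir <- require_stage_outputs(config, "generate", "kfold")
  path <- pipeline_manifest_path(config)
  manifest <- if (file.exists(path)) read_manifest(path) else {
    read_manifest(file.path(raw_dir, "manifest.csv"))
  }
  manifest <- stratified_kfold(manifest, config$split)
  write_manifest(manifest, path)
  list(stage = "kfold", k = config$split$k,
       fold_sizes = as.integer(table(manifest$fold)))
}

# read processed images for a manifest slice at model input size
load_model_images <- function(config, manifest) {
  dir <- stage_dir(config, "lighten")
  lapply(manifest$path, function(p) {
    proc <- derived_path(p, dir)
    img <- read_gray_png(if (file.exists(proc)) proc else p)
    resize_image(img, config$model$input_size)
  })
}

stage_train <- function(config) {
  require_stage_outputs(config, "lighten", "train")
  path <- pipeline_manifest_path(config)
  if (!file.exists(path)) abort_dependency("stage 'train' requires the split manifest")
  manifest <- read_manifest(path)
  train_m <- dplyr::filter(manifest, .data$split == "train")
  if (nrow(train_m) == 0L) abort_data("no training rows in manifest")
  model <- build_hybrid(config$model)
  model <- train_model(model,
                       load_model_images(config, train_m), train_m$label,
                       augment = config$augment)
  readr::write_csv(model$history, file.path(config$out_dir, "history.csv"))
  saveRDS(list(state = get_model_state(model), classes = model$classes,
               config = config$model),
          file.path(config$out_dir, "model_weights.rds"))
  list(stage = "train", epochs = nrow(model$history),
       final_train_accuracy = model$history$train_accuracy[nrow(model$history)])
}

stage_evaluate <- function(config) {
  path <- pipeline_manifest_path(config)
  wpath <- file.path(config$out_dir, "model_weights.rds")
  if (!file.exists(path) || !file.exists(wpath)) {
    abort_dependency("stage 'evaluate' requires split manifest and trained weights")
  }
  manifest <- read_manifest(path)
  test_m <- dplyr::filter(manifest, .data$split == "test")
  saved <- readRDS(wpath)
  model <- build_hybrid(saved$config)
  set_model_state(model, saved$state)
  model$classes <- saved$classes
  pred <- predict_model(model, load_model_images(config, test_m))
  cm <- confusion_from_predictions(test_m$label, pred$label,
                                   sort(unique(manifest$label)))
  met <- metrics_from_confusion(cm)
  readr::write_csv(tidy(met), file.path(config$out_dir, "metrics.csv"))
  utils::write.csv(unclass(cm), file.path(config$out_dir, "confusion.csv"))
  list(stage = "evaluate", accuracy = met$accuracy,
       macro_f1 = met$macro_f1)
}

#' Fit/predict adapters for cross-validating the hybrid model
#'
#' Builds `fit_fun`/`predict_fun` closures for [run_cross_validation()]
#' that read images from disk, train a fresh hybrid model per fold, and
#' predict held-out labels.
#'
#' @param model_cfg A [model_config()].
#' @param augment An [augment_config()] or `NULL`.
#' @param loader `function(manifest) -> list of grayscale matrices` at the
#'   model input size.
#' @return List with `fit_fun` and `predict_fun`.
#' @export
hybrid_cv_functions <- function(model_cfg, augment = NULL, loader) {
  list(
    fit_fun = function(train_m) {
      model <- build_hybrid(model_cfg)
      train_model(model, loader(train_m), train_m$label, augment = augment)
    },
    predict_fun = function(model, test_m) {
      predict_model(model, loader(test_m))$label
    })
}
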
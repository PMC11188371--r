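#' Default pipeline configuration
#'
#' Builds the configuration tree for the end-to-end study:
#' generate -> preprocess -> extract -> train -> evaluate. All stage seeds
#' are derived deterministically from the master `seed`. Any part can be
#' overridden via `read_run_config()` (YAML) or by passing a modified list.
#'
#' @param seed master seed
#' @param out_dir output directory for all stage artifacts
#' @param n dataset size (the study corpus size by default)
#' @param deep_models character vector among `MLP_1`, `MLP_2`, `CNN`
#' @param epochs named list overriding per-model epoch counts
#' @param use_truth_masks bypass GrabCut and use the generator's truth masks
#'   (isolates the model study from segmentation error)
#' @return list of class `fw_run_config`
#' @export
run_config <- function(seed = 1, out_dir = "fw_run", n = 376,
                       deep_models = c("MLP_1", "MLP_2", "CNN"),
                       epochs = list(), use_truth_masks = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    dataset = list(n = as.integer(n), law = unclass(allometric_law()),
                   synth = synth_config()),
    preprocess = list(grabcut_iters = 5, median_kernel = 5,
                      target_size = c(616, 820),
                      use_truth_masks = isTRUE(use_truth_masks)),
    split = list(train_fraction = 0.7),
    models = list(conventional = TRUE, deep = deep_models,
                  epochs = utils::modifyList(
                    list(MLP_1 = 400, MLP_2 = 500, CNN = 300), epochs)),
    inference_repetitions = 10)
  class(cfg) <- "fw_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [run_config()];
#' everything else keeps its default, so minimal configs stay minimal.
#'
#' @param path YAML file
#' @param seed optional master-seed override
#' @param out_dir optional output-directory override
#' @return list of class `fw_run_config`
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(run_config()), y)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  class(cfg) <- "fw_run_config"
  cfg
}

STAGES <- c("generate", "preprocess", "extract", "train", "evaluate")

stage_paths <- function(cfg) {
  o <- cfg$out_dir
  list(data = file.path(o, "data"),
       manifest_csv = file.path(o, "data", "manifest.csv"),
       pred_masks = file.path(o, "pred_masks"),
       features_csv = file.path(o, "features.csv"),
       models = file.path(o, "models"),
       report = file.path(o, "report"),
       run_manifest = file.path(o, "pipeline_manifest.json"))
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

read_run_manifest <- function(cfg) {
  p <- stage_paths(cfg)$run_manifest
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

write_run_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, stage_paths(cfg)$run_manifest,
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Executes a single stage against the configuration's output directory.
#' Each stage records a manifest entry (its configuration hash, seed and
#' duration); re-running a stage whose hash matches and whose outputs exist
#' is skipped, making runs resumable and idempotent. A stage whose upstream
#' outputs are missing raises a dependency error naming the stage to run.
#'
#' @param stage one of `generate`, `preprocess`, `extract`, `train`,
#'   `evaluate`
#' @param config an [run_config()]
#' @return invisibly, the stage's primary output (path or object)
#' @export
run_stage <- function(stage, config = run_config()) {
  stage <- match.arg(stage, STAGES)
  p <- stage_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_run_manifest(config)
  relevant <- switch(stage,
    generate = config[c("seed", "dataset")],
    preprocess = config[c("seed", "dataset", "preprocess")],
    extract = config[c("seed", "dataset", "preprocess")],
    train = config[c("seed", "dataset", "preprocess", "split", "models")],
    evaluate = config)
  h <- config_hash(relevant)
  done <- !is.null(manifest[[stage]]) &&
    identical(manifest[[stage]]$hash, as.character(h)) &&
    stage_outputs_exist(stage, p)
  if (done) {
    message(sprintf("stage %s: outputs up to date, skipping", stage))
    return(invisible(NULL))
  }
  t0 <- proc.time()[["elapsed"]]
  out <- switch(stage,
                generate = stage_generate(config, p),
                preprocess = stage_preprocess(config, p),
                extract = stage_extract(config, p),
                train = stage_train(config, p),
                evaluate = stage_evaluate(config, p))
  manifest[[stage]] <- list(hash = as.character(h), seed = config$seed,
                            duration_s = round(proc.time()[["elapsed"]] - t0, 2))
  write_run_manifest(config, manifest)
  invisible(out)
}

stage_outputs_exist <- function(stage, p) {
  switch(stage,
         generate = file.exists(p$manifest_csv),
         preprocess = dir.exists(p$pred_masks),
         extract = file.exists(p$features_csv),
         train = file.exists(file.path(p$models, "split.json")),
         evaluate = file.exists(file.path(p$report, "report.json")))
}

require_upstream <- function(ok, stage, needed) {
  if (!ok) fw_dependency_error("stage '%s' requires outputs of stage '%s'",
                               stage, needed)
}

stage_generate <- function(cfg, p) {
  law <- do.call(allometric_law, cfg$dataset$law)
  sc <- cfg$dataset$synth
  generate_dataset(cfg$dataset$n, law,
                   seed = derive_seed(cfg$seed, "generate"),
                   out_dir = p$data, config = sc)
  message(sprintf("stage generate: %d samples -> %s", cfg$dataset$n, p$data))
  p$data
}

stage_preprocess <- function(cfg, p) {
  require_upstream(file.exists(p$manifest_csv), "preprocess", "generate")
  mf <- read.csv(p$manifest_csv)
  dir.create(p$pred_masks, recursive = TRUE, showWarnings = FALSE)
  n_empty <- 0L
  for (id in mf$sample_id) {
    dst <- file.path(p$pred_masks, paste0(id, "_mask.png"))
    if (cfg$preprocess$use_truth_masks) {
      src <- file.path(p$data, "masks", paste0(id, "_mask.png"))
      file.copy(src, dst, overwrite = TRUE)
      next
    }
    img <- png::readPNG(file.path(p$data, "images", paste0(id, ".png")))
    img <- resize_to_standard(img, cfg$preprocess$target_size[1],
                              cfg$preprocess$target_size[2])
    seg <- tryCatch(
      select_target_component(segment_plant(
        img, grabcut_iters = cfg$preprocess$grabcut_iters,
        median_kernel = cfg$preprocess$median_kernel)),
      fw_segmentation_empty = function(e) NULL)
    if (is.null(seg)) {  # fall back to the truth mask in synthetic runs
      n_empty <- n_empty + 1L
      file.copy(file.path(p$data, "masks", paste0(id, "_mask.png")), dst,
                overwrite = TRUE)
    } else {
      png::writePNG(seg$mask * 1, dst)
    }
  }
  message(sprintf("stage preprocess: %d masks (%d empty-segmentation fallbacks)",
                  nrow(mf), n_empty))
  p$pred_masks
}

stage_extract <- function(cfg, p) {
  require_upstream(dir.exists(p$pred_masks), "extract", "preprocess")
  require_upstream(file.exists(p$manifest_csv), "extract", "generate")
  mf <- read.csv(p$manifest_csv)
  masks <- lapply(mf$sample_id, function(id)
    png::readPNG(file.path(p$pred_masks, paste0(id, "_mask.png"))) > 0.5)
  feats <- extract_features_batch(masks, mf$sample_id)
  feats <- merge(feats, mf[, c("sample_id", "weight_g")], by = "sample_id",
                 sort = TRUE)
  write.csv(feats, p$features_csv, row.names = FALSE)
  message(sprintf("stage extract: %d/%d samples with features", nrow(feats),
                  nrow(mf)))
  p$features_csv
}

stage_train <- function(cfg, p) {
  require_upstream(file.exists(p$features_csv), "train", "extract")
  feats <- read.csv(p$features_csv)
  dir.create(p$models, recursive = TRUE, showWarnings = FALSE)
  sp <- split_dataset(nrow(feats), cfg$split$train_fraction,
                      seed = derive_seed(cfg$seed, "split"))
  jsonlite::write_json(list(train = feats$sample_id[sp$train],
                            test = feats$sample_id[sp$test]),
                       file.path(p$models, "split.json"))
  train <- feats[sp$train, ]; test <- feats[sp$test, ]
  if (isTRUE(cfg$models$conventional)) {
    grid <- fit_regression_grid(train, test)
    saveRDS(grid, file.path(p$models, "grid.rds"))
    write.csv(grid$results, file.path(p$models, "regression_results.csv"),
              row.names = FALSE)
    grid_store(grid, file.path(p$models, "conventional_models.json"))
  }
  if (length(cfg$models$deep)) {
    imgs <- lapply(feats$sample_id, function(id) {
      img <- png::readPNG(file.path(p$data, "images", paste0(id, ".png")))
      prepare_image_input(resize_to_standard(img,
                                             cfg$preprocess$target_size[1],
                                             cfg$preprocess$target_size[2]))
    })
    for (mdl in cfg$models$deep) {
      spec <- switch(mdl, MLP_1 = build_mlp_manual(),
                     MLP_2 = build_mlp_image(), CNN = build_cnn())
      tc <- train_config(mdl, epochs = cfg$models$epochs[[mdl]],
                         seed = derive_seed(cfg$seed, paste0("train_", mdl)))
      x <- if (spec$input == "features") train else imgs[sp$train]
      fit <- fw_nn(spec, x, train$weight_g, tc)
      saveRDS(fit, file.path(p$models, paste0(mdl, ".rds")))
      write.csv(data.frame(epoch = seq_along(fit$loss), mse_loss = fit$loss),
                file.path(p$models, paste0(mdl, "_loss.csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(model = mdl, epochs = tc$epochs, lr = tc$lr,
             batch_size = tc$batch_size, seed = tc$seed,
             final_loss = tail(fit$loss, 1),
             parameters = nn_param_count(spec)),
        file.path(p$models, paste0(mdl, "_meta.json")), auto_unbox = TRUE)
      message(sprintf("stage train: %s done (final loss %.5f)", mdl,
                      tail(fit$loss, 1)))
    }
  }
  p$models
}

# portable JSON store of the conventional models (coefficients + scalers)
grid_store <- function(grid, path) {
  store <- lapply(grid$models, function(m)
    list(subset = m$subset, degree = m$degree,
         coefficients = as.list(m$coefficients),
         feature_min = as.list(m$feature_scaler$min),
         feature_max = as.list(m$feature_scaler$max),
         target_mean = m$target_scaler$mean, target_sd = m$target_scaler$sd))
  jsonlite::write_json(store, path, auto_unbox = TRUE, digits = 12)
}

stage_evaluate <- function(cfg, p) {
  require_upstream(file.exists(file.path(p$models, "split.json")),
                   "evaluate", "train")
  feats <- read.csv(p$features_csv)
  sp_ids <- jsonlite::read_json(file.path(p$models, "split.json"),
                                simplifyVector = TRUE)
  test <- feats[feats$sample_id %in% sp_ids$test, ]
  grid <- if (file.exists(file.path(p$models, "grid.rds")))
    readRDS(file.path(p$models, "grid.rds"))
  deep <- list()
  for (mdl in cfg$models$deep) {
    f <- file.path(p$models, paste0(mdl, ".rds"))
    if (!file.exists(f)) next
    fit <- readRDS(f)
    x <- if (fit$spec$input == "features") test else {
      lapply(test$sample_id, function(id) {
        img <- png::readPNG(file.path(p$data, "images", paste0(id, ".png")))
        prepare_image_input(resize_to_standard(img,
                                               cfg$preprocess$target_size[1],
                                               cfg$preprocess$target_size[2]))
      })
    }
    pred <- predict(fit, x)
    # repetitions < 1 disables timing (keeps reports byte-reproducible)
    ms <- if (cfg$inference_repetitions >= 1)
      measure_inference_time(fit, x, cfg$inference_repetitions) else NA_real_
    deep[[mdl]] <- eval_report(mdl, test$weight_g, pred, ms)
  }
  corr <- pearson_corr_matrix(feats)
  notes <- sprintf(
    "split %d/%d at fraction %.2f (train size = round(fraction * n))",
    length(sp_ids$train), length(sp_ids$test), cfg$split$train_fraction)
  rep <- build_comparison_report(grid, deep, corr, out_dir = p$report,
                                 notes = notes)
  message("stage evaluate: report written to ", p$report)
  rep
}

#' Run the full pipeline
#'
#' Executes all stages in order under one master seed. Stages whose outputs
#' are already up to date are skipped, so the call is safely re-runnable.
#'
#' @param config an [run_config()]
#' @return the final `fw_report`, invisibly
#' @export
run_all <- function(config = run_config()) {
  out <- NULL
  for (st in STAGES) out <- run_stage(st, config)
  invisible(out)
}
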
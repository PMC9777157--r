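# End-to-end experiment orchestration: phantom generation, preprocessing,
# split, base CNN training, DHL-I, and DHL-II for the configured groupings.
# Every artifact directory carries a provenance stamp (seed + config
# fingerprint) so runs are reconstructible from their outputs.

#' Experiment configuration
#'
#' Defaults are the published hyperparameters at phantom scale: CLAHE clip
#' 5.0 with an 8x8 tile grid on 112x112 inputs, 80/20 hold-out with 10
#' percent validation, Adam(0.001) batch 256, 50 base epochs, 20 fine-tuning
#' epochs, PCA at 0.99, SVM C = 1000 gamma = 0.001. `n_per_grade` and the
#' epoch counts are the natural knobs for quick runs.
#'
#' @param n_per_grade phantoms per KL grade (length 5 or scalar).
#' @param image_size phantom size in pixels.
#' @param noise_sd phantom noise standard deviation.
#' @param preproc a [preproc_config()].
#' @param split a [split_spec()] (its seed is overridden by `seed`).
#' @param base_epochs,tl_epochs,batch_size training budget.
#' @param schemes character vector of DHL-II groupings to run.
#' @param variance_target,C,gamma DHL head hyperparameters.
#' @param seed global experiment seed.
#' @param out_dir artifact directory.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(n_per_grade = 200L, image_size = c(224, 224),
                              noise_sd = 15, preproc = preproc_config(),
                              split = split_spec(),
                              base_epochs = 50L, tl_epochs = 20L,
                              batch_size = 256L,
                              schemes = c("TWO", "THREE", "FOUR"),
                              variance_target = 0.99, C = 1000, gamma = 0.001,
                              seed = 1L, out_dir = tempfile("kneedhl_run")) {
  if (length(n_per_grade) == 1) n_per_grade <- rep(n_per_grade, 5)
  schemes <- toupper(schemes)
  for (s in schemes) {
    if (!s %in% c("FOUR", "THREE", "TWO")) {
      stop_kneedhl(sprintf("invalid DHL-II scheme '%s'", s), "kneedhl_config_error")
    }
  }
  structure(list(n_per_grade = as.integer(n_per_grade), image_size = image_size,
                 noise_sd = noise_sd, preproc = preproc, split = split,
                 base_epochs = as.integer(base_epochs),
                 tl_epochs = as.integer(tl_epochs),
                 batch_size = as.integer(batch_size), schemes = schemes,
                 variance_target = variance_target, C = C, gamma = gamma,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path JSON file with (a subset of) [experiment_config()]'s fields;
#'   `preproc` and `split` given as nested objects.
#' @return an `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_kneedhl(sprintf("config file not found: '%s'", path), "kneedhl_config_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_kneedhl(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
                 "kneedhl_config_error")
  }
  if (!is.null(raw$preproc)) raw$preproc <- do.call(preproc_config, as.list(raw$preproc))
  if (!is.null(raw$split)) raw$split <- do.call(split_spec, as.list(raw$split))
  do.call(experiment_config, raw)
}

config_fingerprint <- function(config) {
  ser <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  fnv1a_hash(as.character(ser))
}

#' Run a full experiment
#'
#' Pipeline: generate phantoms -> preprocess (resize, CLAHE, rescale) ->
#' stratified hold-out split -> train the base 5-class CNN -> DHL-I -> DHL-II
#' per configured grouping -> metrics. Artifacts written under
#' `config$out_dir`: `data/` (PNGs + manifest), `split.csv`, `history.csv`,
#' `base_model.rds`, per-scheme results, `metrics.json` and
#' `provenance.json`. Reruns with the same config and seed reproduce the
#' manifests and metrics.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list with the trained model, per-pipeline
#'   `dhl_result`s and the test-set metrics of the raw CNN.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (verbose) message(sprintf(...))
  fp <- config_fingerprint(config)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = fp,
         config = config[setdiff(names(config), "out_dir")]),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

  log_stage("[generate-data] %s phantoms", sum(config$n_per_grade))
  dataset <- generate_dataset(config$n_per_grade, seed = config$seed,
                              out_dir = file.path(config$out_dir, "data"),
                              image_size = config$image_size,
                              noise_sd = config$noise_sd)

  spl <- config$split
  spl$seed <- config$seed
  dataset <- holdout_split(dataset, spl)
  write.csv(cbind(dataset$records, config_hash = fp, seed = config$seed),
            file.path(config$out_dir, "split.csv"), row.names = FALSE, quote = FALSE)

  log_stage("[preprocess] resize %dx%d + CLAHE", config$preproc$target_size[1],
            config$preproc$target_size[2])
  parts <- lapply(c(train = "train", valid = "valid", test = "test"),
                  function(s) {
                    inp <- split_inputs(dataset, s, config$preproc)
                    list(images = inp$images, labels = inp$grades)
                  })
  log_stage("[split] train %d / valid %d / test %d", length(parts$train$labels),
            length(parts$valid$labels), length(parts$test$labels))

  log_stage("[train-base] %d epochs, batch %d", config$base_epochs, config$batch_size)
  model <- build_base_cnn(5L, seed = config$seed)
  model <- train_model(model, parts$train$images, parts$train$labels,
                       validation = parts$valid, config = train_config(
                         epochs = config$base_epochs, batch_size = config$batch_size,
                         seed = config$seed, verbose = verbose))
  write.csv(cbind(model$history, config_hash = fp, seed = config$seed),
            file.path(config$out_dir, "history.csv"), row.names = FALSE, quote = FALSE)
  saveRDS(model, file.path(config$out_dir, "base_model.rds"))

  cnn_pred <- predict_classes(model, parts$test$images)
  cnn_metrics <- metrics_report(parts$test$labels, cnn_pred, 5L,
                                scores = predict_proba(model, parts$test$images))
  log_stage("[evaluate] raw CNN test accuracy %.1f%%", cnn_metrics$accuracy)

  log_stage("[fit-dhl] DHL-I")
  results <- list(FIVE = run_dhl(model, parts$train, parts$test,
                                 variance_target = config$variance_target,
                                 C = config$C, gamma = config$gamma,
                                 verbose = verbose))
  log_stage("[fit-dhl] DHL-I test accuracy %.1f%%", results$FIVE$accuracy)

  for (s in config$schemes) {
    log_stage("[train-tl] scheme %s, %d epochs", s, config$tl_epochs)
    results[[s]] <- run_dhl2(model, parts$train, parts$test, s,
                             validation = parts$valid, epochs = config$tl_epochs,
                             seed = config$seed,
                             variance_target = config$variance_target,
                             C = config$C, gamma = config$gamma, verbose = verbose)
    log_stage("[train-tl] DHL-II %s test accuracy %.1f%%", s, results[[s]]$accuracy)
  }

  summary <- c(
    list(seed = config$seed, config_hash = fp,
         cnn = list(accuracy = cnn_metrics$accuracy)),
    lapply(results, function(r) list(
      accuracy = r$metrics$accuracy,
      macro = r$metrics$macro,
      n_components = r$head$pca$n_components,
      confusion = unclass(r$metrics$confusion))))
  jsonlite::write_json(summary, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  for (s in names(results)) {
    write_metrics_json(results[[s]]$metrics,
                       file.path(config$out_dir, sprintf("metrics_%s.json", s)),
                       extra = list(seed = config$seed, config_hash = fp))
  }
  invisible(list(model = model, results = results, cnn_metrics = cnn_metrics,
                 dataset = dataset, config = config))
}
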
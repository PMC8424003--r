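#' Pipeline configuration
#'
#' Aggregates the constants of every stage with the published values as
#' defaults: 500 Hz / 0.5 Hz highpass / +-1 mV preprocessing, hop of 5 beats
#' for training images and 10 for testing, SGD with learning rate 0.01,
#' momentum 0.9, L2 1e-4, 3 epochs, LRP epsilon 1, duration thresholds
#' 10/15/20/30/60/90/120/Inf s. Serializable to/from YAML.
#'
#' @param preprocessing a [preprocess_config()].
#' @param train_hop,test_hop window hops (5 or 10).
#' @param training a [train_config()].
#' @param lrp an [lrp_config()].
#' @param thresholds_s evaluation duration thresholds in seconds.
#' @param seed master seed for the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocessing = preprocess_config(),
                            train_hop = 5L, test_hop = 10L,
                            training = train_config(),
                            lrp = lrp_config(),
                            thresholds_s = c(10, 15, 20, 30, 60, 90, 120, Inf),
                            seed = 1L) {
  assert_that(train_hop %in% c(5L, 10L) && test_hop %in% c(5L, 10L),
              "window hops are restricted to 5 or 10 beats")
  structure(list(preprocessing = preprocessing, train_hop = as.integer(train_hop),
                 test_hop = as.integer(test_hop), training = training,
                 lrp = lrp, thresholds_s = thresholds_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` the path; `read_pipeline_config` the
#'   configuration.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$preprocessing <- unclass(x$preprocessing)
  x$training <- unclass(x$training)
  x$lrp <- unclass(x$lrp)
  x$thresholds_s <- ifelse(is.infinite(x$thresholds_s), "Inf",
                           as.character(x$thresholds_s))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    preprocessing = do.call(preprocess_config, x$preprocessing),
    train_hop = x$train_hop, test_hop = x$test_hop,
    training = do.call(train_config, x$training),
    lrp = do.call(lrp_config, x$lrp),
    thresholds_s = as.numeric(x$thresholds_s),
    seed = x$seed
  )
}

#' Run the full detection pipeline on a cohort
#'
#' Preprocess every record, train the three-split majority-of-votes ensemble
#' on the training patients (hop 5, augmented windows), then classify the
#' held-out test records with non-overlapping windows, remap decisions to
#' samples and score episodes. With identical inputs, config and seed the
#' run is fully reproducible.
#'
#' @param train_records,test_records lists of [ecg_record()] (raw; the
#'   pipeline preprocesses them).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: when given, writes `metrics.json`,
#'   `predictions.csv` and the model checkpoint (`ensemble.rds`).
#' @return list with `ensemble`, per-record `reports`, pooled `gross`
#'   metrics, and `config`.
#' @export
run_pipeline <- function(train_records, test_records, config = pipeline_config(),
                         out_dir = NULL) {
  prep <- function(r) ensure_beats(preprocess_record(r, config$preprocessing))
  train_prep <- purrr::map(train_records, prep)
  test_prep <- purrr::map(test_records, prep)
  cfg_train <- config$training
  cfg_train$seed <- config$seed
  ens <- train_three_splits(train_prep, cfg_train, hop_beats = config$train_hop)
  reports <- purrr::map(test_prep, function(r) {
    evaluate_record(ens, r, hop_beats = config$test_hop,
                    thresholds_s = config$thresholds_s)
  })
  names(reports) <- purrr::map_chr(test_prep, "record_id")
  gross <- pool_evaluations(reports, fs = config$preprocessing$target_fs,
                            thresholds_s = config$thresholds_s)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    saveRDS(ens, file.path(out_dir, "ensemble.rds"))
    preds <- purrr::map_dfr(reports, ~ .x$windows[, c(
      "window_id", "record_id", "channel", "label",
      paste0("p_AF_net", 1:3), paste0("vote_net", 1:3), "predicted")])
    readr::write_csv(preds, file.path(out_dir, "predictions.csv"),
                     progress = FALSE)
    metrics <- list(
      validation = ens$validation,
      confusion = gross$confusion,
      ec57 = gross$ec57,
      brief = gross$brief
    )
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(ensemble = ens, reports = reports, gross = gross, config = config)
}
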
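# End-to-end orchestration: simulate or ingest recordings, preprocess, score
# intensity, extract features, train one model per sleep stage, evaluate.

#' Pipeline configuration
#'
#' Exactly one input source: a [synthetic_config()] or a directory of
#' `recNN.edf` + `recNN_hypnogram.csv` + `recNN_events.csv` triplets. The
#' global seed drives every stochastic stage (sham selection, split, SMOTE,
#' CV folds, tuning).
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param input_dir Directory of recordings, or `NULL` when simulating.
#' @param seed Global integer seed.
#' @param highpass_hz,target_fs Preprocessing parameters.
#' @param threshold_mode `"fit"` (quartiles of the data at hand, the default
#'   procedure) or `"fixed"` ([reference_thresholds()]).
#' @param sham_min,sham_max,sham_len_s,sham_clearance_s Sham-window
#'   parameters.
#' @param test_frac,cv_folds,smote_k,rfe_step,n_trials,objective Modelling
#'   parameters (see [split_dataset()], [rfecv_select()], [tune_and_fit()]).
#' @param min_stage_rows Minimum training rows for a stage to get its own
#'   model (default 20; smaller stages are skipped with a warning).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL, seed = 1L,
                            highpass_hz = 0.3, target_fs = 128,
                            threshold_mode = c("fit", "fixed"),
                            sham_min = 10L, sham_max = 14L, sham_len_s = 9,
                            sham_clearance_s = 10,
                            test_frac = 0.2, cv_folds = 5L, smote_k = 5L,
                            rfe_step = 0.2, n_trials = 30L,
                            objective = "mean_cv_accuracy",
                            min_stage_rows = 20L) {
  if (is.null(synthetic) == is.null(input_dir)) {
    stop("exactly one input source: give `synthetic` or `input_dir`")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 seed = as.integer(seed), highpass_hz = highpass_hz,
                 target_fs = target_fs,
                 threshold_mode = match.arg(threshold_mode),
                 sham_min = sham_min, sham_max = sham_max,
                 sham_len_s = sham_len_s,
                 sham_clearance_s = sham_clearance_s,
                 test_frac = test_frac, cv_folds = cv_folds,
                 smote_k = smote_k, rfe_step = rfe_step,
                 n_trials = n_trials, objective = objective,
                 min_stage_rows = min_stage_rows),
            class = "pipeline_config")
}

.load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    sims <- simulate_psg_dataset(config$synthetic)
    return(lapply(sims, function(s) {
      list(recording = s$recording, hypnogram = s$hypnogram,
           events = s$events, ground_truth = s$ground_truth)
    }))
  }
  edfs <- sort(list.files(config$input_dir, pattern = "\\.edf$",
                          full.names = TRUE))
  if (!length(edfs)) stop("no EDF files in ", config$input_dir)
  lapply(edfs, function(path) {
    base <- sub("\\.edf$", "", path)
    ann <- read_annotations(paste0(base, "_hypnogram.csv"),
                            paste0(base, "_events.csv"))
    list(recording = read_recording(path), hypnogram = ann$hypnogram,
         events = ann$events[!ann$events$is_sham, , drop = FALSE],
         ground_truth = NULL)
  })
}

#' Run the full scoring + classification pipeline
#'
#' Simulates or loads recordings; then per recording: preprocess, select
#' sham windows, measure every event's amplitude distance, extract the
#' 136-feature vectors. Thresholds are fitted once over all recordings'
#' non-sham amplitudes (or taken from the reference fixture), levels
#' assigned, the dataset split 80/20 stratified by level, partitioned by
#' sleep stage, and one classifier per stage is SMOTE-balanced, RFE-selected,
#' TPE-tuned, fitted and evaluated on the held-out split. Event counts in
#' and out of every stage are logged via `message()`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Directory for artifacts (scored events CSV, feature CSV,
#'   report JSON), or `NULL` to skip writing.
#' @return A list of class `pipeline_result`: `report` (a `stage_report`),
#'   `models`, `specs`, `thresholds`, `features`, `scored`, `split`,
#'   `drop_log`, `ground_truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .load_inputs(config)
  message(sprintf("loaded %d recording(s)", length(inputs)))

  scored_parts <- list(); feature_parts <- list(); drop_parts <- list()
  gt_parts <- list()
  for (r in seq_along(inputs)) {
    inp <- inputs[[r]]
    prep <- preprocess_recording(inp$recording,
                                 highpass_hz = config$highpass_hz,
                                 target_fs = config$target_fs)
    sham <- select_sham_windows(inp$hypnogram, inp$events,
                                seed = config$seed + 1000L + r,
                                sham_min = config$sham_min,
                                sham_max = config$sham_max,
                                sham_len_s = config$sham_len_s,
                                clearance_s = config$sham_clearance_s)
    all_ev <- rbind(inp$events, sham)
    all_ev <- all_ev[order(all_ev$onset), , drop = FALSE]
    measured <- measure_amplitudes(prep, all_ev)
    measured$recording <- r
    measured$level <- NA_integer_            # assigned after the global fit
    feats <- build_feature_matrix(prep, measured,
                                  id_prefix = sprintf("r%02d_ev", r))
    message(sprintf(
      "recording %d: %d arousals + %d shams -> %d measured, %d feature rows (%d dropped)",
      r, nrow(inp$events), nrow(sham), nrow(measured), nrow(feats),
      nrow(attr(feats, "drop_log"))))
    measured$event_id <- sprintf("r%02d_ev%04d", r, seq_len(nrow(measured)))
    scored_parts[[r]] <- measured
    feature_parts[[r]] <- feats
    drop_parts[[r]] <- attr(feats, "drop_log")
    if (!is.null(inp$ground_truth) && nrow(inp$ground_truth)) {
      gt <- inp$ground_truth
      gt$recording <- r
      gt_parts[[length(gt_parts) + 1L]] <- gt
    }
  }
  scored <- do.call(rbind, scored_parts)
  features <- do.call(rbind, feature_parts)
  drop_log <- do.call(rbind, drop_parts)

  thresholds <- if (config$threshold_mode == "fixed") reference_thresholds()
                else fit_quartile_thresholds(scored$amplitude[!scored$is_sham])
  scored$level <- vapply(seq_len(nrow(scored)), function(i) {
    assign_level(scored$amplitude[i], thresholds,
                 is_sham = scored$is_sham[i])
  }, integer(1))
  features$level <- scored$level[match(features$event_id, scored$event_id)]
  message(sprintf("scored %d events; level counts: %s", nrow(scored),
                  paste(sprintf("%s:%d", names(table(scored$level)),
                                table(scored$level)), collapse = " ")))

  split <- split_dataset(features, test_frac = config$test_frac,
                         seed = config$seed)
  message(sprintf("split: %d train / %d test", nrow(split$train),
                  nrow(split$test)))

  stages_present <- intersect(c("REM", "N1", "N2", "N3"),
                              unique(split$train$stage))
  specs <- list(); models <- list(); stage_results <- list()
  for (stg in stages_present) {
    tr <- split$train[split$train$stage == stg, , drop = FALSE]
    te <- split$test[split$test$stage == stg, , drop = FALSE]
    if (nrow(tr) < config$min_stage_rows || length(unique(tr$level)) < 2L ||
        nrow(te) == 0L) {
      warning(sprintf("stage %s: too little data (%d train, %d test); skipped",
                      stg, nrow(tr), nrow(te)))
      next
    }
    bal <- oversample_minority(tr, k_neighbors = config$smote_k,
                               seed = config$seed + 10L)
    message(sprintf("stage %s: %d train rows -> %d after SMOTE, %d test rows",
                    stg, nrow(tr), nrow(bal), nrow(te)))
    spec <- choose_stage_config(stats::setNames(list(bal), stg),
                                cv_folds = config$cv_folds,
                                seed = config$seed + 20L,
                                step = config$rfe_step)[[stg]]
    model <- tune_and_fit(bal, spec, n_trials = config$n_trials,
                          objective = config$objective,
                          seed = config$seed + 30L)
    pred <- predict_levels(model, te)
    specs[[stg]] <- model$spec
    models[[stg]] <- model
    stage_results[[stg]] <- list(y_true = te$level, y_pred = pred$levels,
                                 scores = pred$scores,
                                 test_ids = te$event_id,
                                 train_ids = tr$event_id)
    message(sprintf("stage %s: %s with %d features, cv value %.3f",
                    stg, spec$classifier_kind,
                    length(spec$selected_features), model$cv_value))
  }
  if (!length(stage_results)) stop("no stage had enough data to train on")
  report <- aggregate_report(stage_results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scored, file.path(out_dir, "scored_events.csv"),
                     row.names = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    write_report(report_as_list(report), file.path(out_dir, "report.json"))
  }

  structure(list(report = report, models = models, specs = specs,
                 thresholds = thresholds, features = features,
                 scored = scored, split = split,
                 stage_results = stage_results, drop_log = drop_log,
                 ground_truth = if (length(gt_parts))
                   do.call(rbind, gt_parts) else NULL),
            class = "pipeline_result")
}
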
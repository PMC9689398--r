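#' Predict the future fetal state from forecasted signals
#'
#' The headline capability: both channels are forecast `horizon_steps` ahead
#' with their trained LSTM models, the forecasts are appended to the
#' observed record, FIGO-style features are extracted from the extended
#' series, and the abstaining ensemble classifies them into non-acidosis
#' (0), acidosis (1) or `"unsure"`.
#'
#' By default features are extracted on the observed history plus the
#' forecast (`window = "full"`): a 2-min forecast window alone cannot host
#' the 2--5 min prolonged events. `window = "forecast"` restricts feature
#' extraction to the forecasted segment.
#'
#' @param record a [ctg_record()] (long enough for both lookbacks).
#' @param fhr_model,uc_model trained [train_forecaster()] objects.
#' @param ensemble a [ctg_ensemble()].
#' @param horizon_steps forecast horizon in samples (480 = 2 min, 960 =
#'   4 min); 0 classifies the observed record directly.
#' @param window `"full"` or `"forecast"`.
#' @return Object of class `future_state` with the consensus, per-learner
#'   votes, the feature vector used and the forecast segments.
#' @export
predict_future_state <- function(record, fhr_model, uc_model, ensemble,
                                 horizon_steps = 480L,
                                 window = c("full", "forecast")) {
  window <- match.arg(window)
  stopifnot(inherits(record, "ctg_record"))
  if (horizon_steps < 0)
    stop("predict_future_state: horizon must be nonnegative", call. = FALSE)
  if (horizon_steps > 0 &&
      (!inherits(fhr_model, "ctg_forecaster") ||
       !inherits(uc_model, "ctg_forecaster")))
    stop("predict_future_state: trained FHR and UC forecasters required",
         call. = FALSE)
  if (!inherits(ensemble, "ctg_ensemble"))
    stop("predict_future_state: an ensemble classifier is required",
         call. = FALSE)
  rec <- interpolate_gaps(record, 15)
  fhr_obs <- rec$fhr
  uc_obs <- rec$uc
  fhr_obs[is.na(fhr_obs)] <- mean(fhr_obs, na.rm = TRUE)
  uc_obs[is.na(uc_obs)] <- mean(uc_obs, na.rm = TRUE)
  if (horizon_steps > 0) {
    fhr_fc <- pmin(pmax(forecast_recursive(fhr_model, fhr_obs,
                                           horizon_steps), 30), 250)
    uc_fc <- pmax(forecast_recursive(uc_model, uc_obs, horizon_steps), 0)
  } else {
    fhr_fc <- numeric(0)
    uc_fc <- numeric(0)
  }
  if (window == "full" || horizon_steps == 0) {
    ext <- ctg_record(c(fhr_obs, fhr_fc), c(uc_obs, uc_fc),
                      ph = NA, record_id = paste0(record$record_id, "+fc"))
  } else {
    ext <- ctg_record(fhr_fc, uc_fc, ph = NA,
                      record_id = paste0(record$record_id, "+fc"))
  }
  fv <- extract_features(ext)
  dec <- predict(ensemble, as.data.frame(fv))
  structure(list(record_id = record$record_id,
                 horizon_steps = as.integer(horizon_steps),
                 horizon_s = horizon_steps / CTG_HZ,
                 per_learner = as.list(dec[1L, names(ensemble$models)]),
                 consensus = dec$consensus[1L],
                 feature_vector_used = fv$features,
                 forecast_segments = list(fhr = fhr_fc, uc = uc_fc),
                 window = window),
            class = "future_state")
}

#' @export
print.future_state <- function(x, ...) {
  lab <- c("0" = "non-acidosis (0)", "1" = "acidosis (1)",
           unsure = "Unsure")[x$consensus]
  cat(sprintf("Future fetal state for '%s' at +%.0f s (%d steps): %s\n",
              x$record_id, x$horizon_s, x$horizon_steps, lab))
  votes <- paste(names(x$per_learner), unlist(x$per_learner), sep = "=",
                 collapse = ", ")
  cat("  per-learner votes:", votes, "\n")
  invisible(x)
}

#' Configuration for the integrated desk-scale experiment
#'
#' @param n cohort size; `acidotic_fraction` the class balance.
#' @param duration_s record length in seconds.
#' @param test_size held-out test records.
#' @param learners which base learners to train.
#' @param ensemble_members learners forming the future-state ensemble.
#' @param horizons future-state horizons in samples.
#' @param fast_forecaster use the desk-scale lookback for the showcase
#'   forecasters.
#' @param forecast_epochs training epochs for the showcase forecasters.
#' @param seed root seed for every stage.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n = 94L, acidotic_fraction = 0.5,
                              duration_s = 1800, test_size = 24L,
                              learners = c("svm", "random_forest",
                                           "neural_net", "kmeans"),
                              ensemble_members = c("random_forest",
                                                   "neural_net"),
                              horizons = c(480L, 960L),
                              fast_forecaster = TRUE,
                              forecast_epochs = 12L,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$test_size >= cfg$n)
    stop("experiment_config: test_size must be smaller than the cohort",
         call. = FALSE)
  if (!all(cfg$ensemble_members %in% cfg$learners))
    stop("experiment_config: ensemble members must be trained learners",
         call. = FALSE)
  class(cfg) <- "experiment_config"
  cfg
}

#' Run the integrated desk-scale study
#'
#' One command reproduces the whole pipeline on synthetic data: simulate a
#' labeled cohort, extract and prune features, make a stratified train/test
#' split, train the base learners with grid-searched 5-fold CV, evaluate
#' every unanimous-vote combination with its coverage and accuracy, compute
#' the Pareto front, train per-channel LSTM forecasters on one acidotic and
#' one non-acidotic showcase record, and classify the forecasted future at
#' each horizon. Deterministic given `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param out_json optional path; when given, the report is also written as
#'   canonical JSON (byte-identical across reruns with the same seed).
#' @return Object of class `ctg_experiment`.
#' @export
run_experiment <- function(config = experiment_config(), out_json = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_experiment: stage '", name, "' failed (seed ", config$seed,
           "): ", conditionMessage(e), call. = FALSE))
  }
  cohort <- stage("simulate",
                  generate_cohort(config$n, config$acidotic_fraction,
                                  duration_s = config$duration_s,
                                  seed = config$seed))
  feats <- stage("extract", cohort_features(cohort))
  labels <- feats$label
  pruned <- stage("prune", prune_rare_features(feats))
  fcols <- setdiff(names(pruned$table), c("record_id", "ph", "label"))
  x <- pruned$table[fcols]
  split <- stage("split",
                 split_train_test(x, labels, config$test_size, config$seed))
  models <- stage("train", {
    ms <- lapply(config$learners, function(kind)
      train_learner(kind, x[split$train_idx, ], labels[split$train_idx],
                    seed = config$seed))
    names(ms) <- config$learners
    ms
  })
  combos <- stage("combinations",
                  evaluate_combinations(models, x[split$test_idx, ],
                                        labels[split$test_idx]))
  front <- stage("pareto", pareto_front(combos))
  ens <- ctg_ensemble(models[config$ensemble_members])
  combo_sets <- lapply(strsplit(combos$combo, "/", fixed = TRUE), sort)
  ens_row <- combos[vapply(combo_sets, identical,
                           TRUE, sort(config$ensemble_members)), ]

  ## showcase forecasting + future state, one record per class
  class_of <- vapply(cohort, function(r) r$truth$class_label, "")
  showcase_idx <- c(acidotic = which(class_of == "acidotic")[1L],
                    non_acidotic = which(class_of == "non_acidotic")[1L])
  future <- list()
  forecast_reports <- list()
  for (nm in names(showcase_idx)) {
    stage(paste0("forecast_", nm), {
      rec <- interpolate_gaps(cohort[[showcase_idx[[nm]]]]$record, 15)
      fhr <- rec$fhr; fhr[is.na(fhr)] <- mean(fhr, na.rm = TRUE)
      uc <- rec$uc; uc[is.na(uc)] <- mean(uc, na.rm = TRUE)
      presets <- forecaster_presets(fast = config$fast_forecaster,
                                    epochs = config$forecast_epochs,
                                    seed = config$seed)
      key <- if (nm == "acidotic") c("fhr_acidotic", "uc_acidotic") else
        c("fhr_non_acidotic", "uc_non_acidotic")
      fhr_m <- train_forecaster(fhr, presets[[key[1L]]], smooth_window_s = 0)
      uc_m <- train_forecaster(uc, presets[[key[2L]]], smooth_window_s = 0)
      forecast_reports[[nm]] <- list(fhr = fhr_m$report, uc = uc_m$report)
      future[[nm]] <- lapply(config$horizons, function(h)
        predict_future_state(cohort[[showcase_idx[[nm]]]]$record,
                             fhr_m, uc_m, ens, h))
    })
  }
  future_table <- do.call(rbind, lapply(names(future), function(nm)
    do.call(rbind, lapply(future[[nm]], function(fs)
      data.frame(scenario = nm, horizon_steps = fs$horizon_steps,
                 consensus = fs$consensus, stringsAsFactors = FALSE)))))

  report <- structure(list(
    config = unclass(config),
    cohort = list(n = config$n,
                  n_acidotic = sum(labels == 1L),
                  n_non_acidotic = sum(labels == 0L)),
    dropped_features = pruned$dropped,
    cv_metrics = lapply(models, function(m)
      if (is.null(m$cv_metrics)) NULL else unclass(m$cv_metrics)),
    combinations = combos,
    pareto_front = front,
    ensemble = list(members = config$ensemble_members,
                    n_classified = ens_row$n_classified,
                    accuracy_on_classified = ens_row$accuracy),
    forecast_reports = forecast_reports,
    future_states = future_table),
    class = "ctg_experiment")
  if (!is.null(out_json)) write_experiment_json(report, out_json)
  report
}

#' @export
print.ctg_experiment <- function(x, ...) {
  cat("Integrated CTG study on a synthetic cohort of", x$cohort$n,
      sprintf("records (%d acidotic / %d non-acidotic)\n",
              x$cohort$n_acidotic, x$cohort$n_non_acidotic))
  if (length(x$dropped_features))
    cat("  pruned rare features:", paste(x$dropped_features, collapse = ", "),
        "\n")
  cat("  combination coverage/accuracy (test set):\n")
  print(x$combinations, row.names = FALSE)
  cat("  Pareto front:\n")
  print(x$pareto_front, row.names = FALSE)
  cat(sprintf("  %s ensemble: %d classified, accuracy %.2f%%\n",
              paste(x$ensemble$members, collapse = "/"),
              x$ensemble$n_classified, x$ensemble$accuracy_on_classified))
  cat("  future fetal state:\n")
  print(x$future_states, row.names = FALSE)
  invisible(x)
}

write_experiment_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           null = "null", dataframe = "rows", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
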
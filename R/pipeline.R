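# End-to-end pipeline: simulate -> preprocess -> MEWS -> train -> evaluate ->
# explain, with a manifest recording configuration, seeds and per-stage row
# counts so a run is auditable and exactly reproducible.

#' Pipeline run configuration
#'
#' Bundles every stage's settings and seeds. Defaults give a small
#' demonstration run (2,000 patients, reduced encoder) that completes on one
#' CPU in minutes; the published full-scale settings are available from
#' [tews_constants()] and [model_config()] defaults.
#'
#' @param n_patients Cohort size.
#' @param prevalence Adverse-event prevalence (default 0.037).
#' @param features `"full"` or `"vitals_only"`.
#' @param cadence_minutes Prediction cadence.
#' @param horizon_hours,window_hours Label horizon and look-back window.
#' @param outcomes Event types to fit (default `"vasopressor"`).
#' @param model Named list of [model_config()] overrides (e.g.
#'   `list(d_model = 32L, n_layers = 2L, epochs = 10L)`).
#' @param neg_windows_per_patient Training subsample: windows kept per
#'   event-free patient (all windows of event patients are kept).
#' @param n_boot Bootstrap resamples for evaluation.
#' @param seeds Named integer seeds per stochastic stage
#'   (`simulate`, `split`, `model`, `sample`, `boot`).
#' @return A `tews_run_config` list.
#' @export
run_config <- function(n_patients = 2000L, prevalence = 0.037,
                       features = c("full", "vitals_only"),
                       cadence_minutes = 60, horizon_hours = 24,
                       window_hours = 48, outcomes = "vasopressor",
                       model = list(d_model = 32L, n_layers = 2L,
                                    d_ff = 64L, epochs = 10L,
                                    batch_size = 64L, learning_rate = 1e-3,
                                    pooling = "mean",
                                    loss_weights = "auto"),
                       neg_windows_per_patient = 1L, n_boot = 200L,
                       seeds = c(simulate = 1L, split = 2L, model = 3L,
                                 sample = 4L, boot = 5L)) {
  features <- match.arg(features)
  stopifnot(all(outcomes %in% AE_TYPES),
            all(c("simulate", "split", "model", "sample", "boot") %in%
                  names(seeds)))
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    features = features, cadence_minutes = cadence_minutes,
    horizon_hours = horizon_hours, window_hours = window_hours,
    outcomes = outcomes, model = model,
    neg_windows_per_patient = as.integer(neg_windows_per_patient),
    n_boot = as.integer(n_boot), seeds = seeds
  ), class = "tews_run_config")
}

#' Training-window subsample
#'
#' Keeps every eligible window of patients who experience the outcome and up
#' to `neg_per_patient` eligible windows per event-free patient; this caps the
#' heavily redundant negative windows while preserving all positive temporal
#' context.
#'
#' @param windows A `tews_windows`.
#' @param outcome Event type.
#' @param patient_ids Patients to draw from (e.g. the train partition).
#' @param neg_per_patient Windows kept per event-free patient.
#' @param seed Sampling seed.
#' @return Integer vector of window ids.
#' @export
select_train_windows <- function(windows, outcome, patient_ids,
                                 neg_per_patient = 1L, seed = 1L) {
  frame <- outcome_frame(windows, outcome)
  frame <- frame[frame$patient_id %in% patient_ids, ]
  pos_patients <- unique(frame$patient_id[frame$label == 1])
  keep_pos <- frame$window_id[frame$patient_id %in% pos_patients]
  neg <- frame[!frame$patient_id %in% pos_patients, ]
  keep_neg <- withr::with_seed(seed, {
    neg |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_sample(n = neg_per_patient) |>
      dplyr::ungroup() |>
      dplyr::pull(.data$window_id)
  })
  sort(c(keep_pos, keep_neg))
}

#' Run the full pipeline
#'
#' Simulate a cohort, build windows, compute the MEWS baseline, train one
#' model per requested outcome, evaluate both scorers at visit level on the
#' test partition (Youden threshold for the model, alarm threshold 5 for
#' MEWS, matched-sensitivity comparison), explain the highest-risk test
#' windows, and write all artifacts plus a manifest into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with the cohort, windows, models, evaluation
#'   reports and the manifest. Artifacts and `manifest.json` are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "tews_run_config"))
  parent <- dirname(out_dir)
  if (!dir.exists(parent)) {
    stop("output location does not exist: ", parent, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(),
                   started = format(Sys.time(), tz = "UTC"))

  cohort <- generate_cohort(cohort_spec(config$n_patients,
                                        prevalence = config$prevalence,
                                        seed = config$seeds[["simulate"]]))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  manifest$stages$simulate <- list(
    n_patients = nrow(cohort$static), n_events = nrow(cohort$events),
    n_outcome_rows = nrow(cohort$outcomes),
    data_hash = rlang::hash(cohort))

  split <- split_cohort(cohort, seed = config$seeds[["split"]])
  windows <- build_windows(cohort, feature_set(config$features),
                           cadence_minutes = config$cadence_minutes,
                           horizon_hours = config$horizon_hours,
                           window_hours = config$window_hours)
  manifest$stages$preprocess <- list(
    n_windows = nrow(windows$index), n_values = nrow(windows$values),
    n_removed = sum(windows$n_removed$n_removed),
    data_hash = rlang::hash(windows$values))

  mews <- mews_series(cohort, windows$index[, c("patient_id",
                                                "prediction_time")],
                      threshold = tews_constants()$mews_threshold)
  readr::write_csv(mews, file.path(out_dir, "mews_scores.csv"))
  manifest$stages$mews <- list(n_scores = nrow(mews),
                               data_hash = rlang::hash(mews$mews))

  test_ids <- split$patient_id[split$partition == "test"]
  models <- list()
  reports <- list()
  for (oc in config$outcomes) {
    cfg <- do.call(model_config, c(list(
      n_features = nrow(windows$features),
      static_dim = ncol(windows$statics) - 1L,
      t_steps = windows$t_steps, seed = config$seeds[["model"]]),
      config$model))
    train_ids <- select_train_windows(
      windows, oc, split$patient_id[split$partition == "train"],
      config$neg_windows_per_patient, config$seeds[["sample"]])
    model <- train_tews(windows, oc, cfg, split,
                        train_window_ids = train_ids)
    models[[oc]] <- model

    pred <- predict(model, windows)
    pred_test <- pred[pred$patient_id %in% test_ids, ]
    visits <- aggregate_visits(pred_test)
    ev_tews <- evaluate_scores(visits, n_boot = config$n_boot,
                               seed = config$seeds[["boot"]],
                               scorer = "tews", outcome = oc)

    frame <- outcome_frame(windows, oc)
    mews_oc <- dplyr::inner_join(
      mews, frame[, c("patient_id", "prediction_time", "label")],
      by = c("patient_id", "prediction_time"))
    mews_visits <- aggregate_visits(
      mews_oc[mews_oc$patient_id %in% test_ids, ], score_col = "mews")
    ev_mews <- evaluate_scores(mews_visits,
                               threshold = tews_constants()$mews_threshold,
                               n_boot = config$n_boot,
                               seed = config$seeds[["boot"]],
                               scorer = "mews", outcome = oc)

    both <- dplyr::inner_join(
      dplyr::rename(visits, tews = "score"),
      dplyr::rename(mews_visits[, c("patient_id", "score")], mews = "score"),
      by = "patient_id")
    cmp <- bootstrap_auroc_test(both, "tews", "mews",
                                n_boot = config$n_boot,
                                seed = config$seeds[["boot"]])
    ref_sens <- confusion_metrics(mews_visits$score, mews_visits$label,
                                  tews_constants()$mews_threshold)$sensitivity
    matched <- tryCatch({
      thr_m <- matched_sensitivity_threshold(visits$score, visits$label,
                                             ref_sens)
      cm <- confusion_metrics(visits$score, visits$label, as.numeric(thr_m))
      list(threshold = as.numeric(thr_m),
           achieved_sensitivity = attr(thr_m, "achieved_sensitivity"),
           false_alarms_per_1000 = cm$false_alarms_per_1000,
           mews_false_alarms_per_1000 = confusion_metrics(
             mews_visits$score, mews_visits$label,
             tews_constants()$mews_threshold)$false_alarms_per_1000)
    }, error = function(e) list(error = conditionMessage(e)))

    top_idx <- pred_test$window_id[order(-pred_test$.pred)][
      seq_len(min(5, nrow(pred_test)))]
    sal <- grad_cam(model, windows, window_ids = top_idx)
    reports[[oc]] <- list(tews = ev_tews, mews = ev_mews, comparison = cmp,
                          matched_sensitivity = matched,
                          top_features = top_features(sal))

    manifest$stages[[paste0("train_", oc)]] <- list(
      n_train_windows = model$provenance$n_train,
      train_positives = model$provenance$train_positives,
      best_epoch = model$best_epoch,
      data_hash = model$provenance$data_hash,
      param_hash = rlang::hash(model$params))
    manifest$stages[[paste0("evaluate_", oc)]] <- list(
      n_test_visits = ev_tews$n_visits,
      tews = stats::setNames(as.list(ev_tews$metrics$estimate),
                             ev_tews$metrics$metric),
      mews = stats::setNames(as.list(ev_mews$metrics$estimate),
                             ev_mews$metrics$metric),
      delta_auroc = cmp$delta_auroc, p_value = cmp$p_value,
      matched_sensitivity = matched)
    report_tbl <- dplyr::bind_rows(tidy(ev_tews), tidy(ev_mews))
    readr::write_csv(report_tbl,
                     file.path(out_dir, paste0("metrics_", oc, ".csv")))
  }

  manifest$config_hash <- rlang::hash(unclass(config))
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <-
    as.character(utils::packageVersion("tewsr"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, split = split, windows = windows,
                 mews = mews, models = models, reports = reports,
                 manifest = manifest))
}
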
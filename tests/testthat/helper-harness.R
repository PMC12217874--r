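# Shared scaled-down study harness used by the acceptance suite. Built once
# and cached: a 5,000-patient synthetic cohort under the default study
# conditions, a reduced transformer (d_model 32, 2 layers, 20 epochs) for the
# vasopressor outcome, and the MEWS baseline on the same prediction grid.
#
# Fixed conventions: cohort seed 1, split seed 2, model seed 3, training
# subsample seed 4, validation subsample seed 5; prediction cadence 60 min;
# training uses every eligible window of event patients plus one window per
# event-free patient; optimiser settings (learning rate 1e-3, batch 64,
# masked-mean pooling) were selected on the validation partition only.

.harness_env <- new.env(parent = emptyenv())

acceptance_harness <- function() {
  if (!is.null(.harness_env$h)) return(.harness_env$h)
  outcome <- "vasopressor"
  cohort <- generate_cohort(cohort_spec(5000, seed = 1))
  split <- split_cohort(cohort, seed = 2)
  windows <- build_windows(cohort, feature_set("full"), cadence_minutes = 60)
  frame <- tewsr:::outcome_frame(windows, outcome)
  tr_pat <- split$patient_id[split$partition == "train"]
  va_pat <- split$patient_id[split$partition == "validation"]
  te_pat <- split$patient_id[split$partition == "test"]

  cfg <- model_config(
    n_features = 13, static_dim = 3, d_model = 32L, n_layers = 2L,
    d_ff = 64L, t_steps = 192L, batch_size = 64L, epochs = 20L,
    learning_rate = 1e-3, loss_weights = "auto", pooling = "mean", seed = 3L)
  model <- train_tews(
    windows, outcome, cfg, split,
    train_window_ids = select_train_windows(windows, outcome, tr_pat, 1L, 4L),
    val_window_ids = select_train_windows(windows, outcome, va_pat, 2L, 5L))

  te_frame <- frame[frame$patient_id %in% te_pat, ]
  pred_test <- predict(model, windows, window_ids = te_frame$window_id)
  tews_visits <- aggregate_visits(pred_test)

  mews <- mews_series(cohort,
                      windows$index[windows$index$patient_id %in% te_pat,
                                    c("patient_id", "prediction_time")])
  mews_lab <- dplyr::inner_join(
    mews, frame[, c("patient_id", "prediction_time", "label")],
    by = c("patient_id", "prediction_time"))
  mews_visits <- aggregate_visits(mews_lab, score_col = "mews")

  .harness_env$h <- list(
    outcome = outcome, cohort = cohort, split = split, windows = windows,
    config = cfg, model = model, pred_test = pred_test,
    tews_visits = tews_visits, mews_visits = mews_visits,
    test_patients = te_pat)
  .harness_env$h
}

# External cohort for the transfer-learning property: same generator with all
# group means shifted by +0.5 group SD (dataset shift in location only).
shifted_external_cohort <- function(n = 3000, seed = 6) {
  vars <- default_variables()
  vars$ae_mean <- vars$ae_mean + 0.5 * vars$ae_sd
  vars$nonae_mean <- vars$nonae_mean + 0.5 * vars$nonae_sd
  # keep means inside the valid ranges (SpO2 caps at 100)
  vars$ae_mean <- pmin(vars$ae_mean, vars$hi - 0.01 * (vars$hi - vars$lo))
  vars$nonae_mean <- pmin(vars$nonae_mean,
                          vars$hi - 0.01 * (vars$hi - vars$lo))
  generate_cohort(cohort_spec(n, variables = vars, seed = seed))
}
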
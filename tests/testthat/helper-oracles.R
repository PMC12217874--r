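# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive loops so they share no code path with the package
# implementations they check.

oracle_bins <- function(events, window_end, features, t_steps = 192L,
                        bin_minutes = 15) {
  nf <- nrow(features)
  X <- matrix(0, t_steps, nf)
  mask <- X
  for (t in seq_len(t_steps)) {
    lo <- window_end - 60 * bin_minutes * (t_steps - t + 1)
    hi <- window_end - 60 * bin_minutes * (t_steps - t)
    for (v in seq_len(nf)) {
      rows <- which(events$variable == features$variable[v] &
                      events$timestamp >= lo & events$timestamp < hi)
      if (length(rows) > 0) {
        # latest timestamp wins; ties broken by input order (later row wins)
        best <- rows[order(events$timestamp[rows],
                           seq_along(rows))][length(rows)]
        X[t, v] <- events$value[best]
        mask[t, v] <- 1
      }
    }
  }
  list(X = X, mask = mask)
}

oracle_labels <- function(outcomes, prediction_time, horizon_hours = 24) {
  labs <- stats::setNames(integer(5), tewsr:::AE_TYPES)
  for (ty in tewsr:::AE_TYPES) {
    ts <- outcomes$timestamp[outcomes$event_type == ty]
    for (e in ts) {
      if (e > prediction_time &&
          e <= prediction_time + horizon_hours * 3600) {
        labs[ty] <- 1L
      }
    }
  }
  labs
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

oracle_youden <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-9) {  # strict improvement => ties keep lowest t
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

oracle_auprc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  ts <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (t in ts) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- tp / n_pos
    prec <- tp / (tp + fp)
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# Direct if-else MEWS scorer, independent of the shipped band table.
oracle_mews <- function(sbp, hr, rr, temp) {
  s <- 0
  if (!is.na(sbp)) {
    s <- s + if (sbp < 71) 3 else if (sbp < 81) 2 else if (sbp < 101) 1
             else if (sbp < 200) 0 else 2
  }
  if (!is.na(hr)) {
    s <- s + if (hr < 41) 2 else if (hr < 51) 1 else if (hr < 101) 0
             else if (hr < 111) 1 else if (hr < 130) 2 else 3
  }
  if (!is.na(rr)) {
    s <- s + if (rr < 9) 2 else if (rr < 15) 0 else if (rr < 21) 1
             else if (rr < 30) 2 else 3
  }
  if (!is.na(temp)) {
    s <- s + if (temp < 35) 2 else if (temp < 38.5) 0 else 2
  }
  s
}

# Hand-built cohort from explicit per-patient pieces.
make_cohort <- function(events, static, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- tibble::tibble(
      patient_id = character(0), event_type = character(0),
      timestamp = as.POSIXct(character(0), tz = "UTC"))
  }
  tewsr:::new_tews_cohort(events, static, outcomes)
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

# One-patient fixture: regular HR/SBP measurements over `los_hours`.
simple_patient <- function(id = "A", los_hours = 2, gap_minutes = 30,
                           arrival = utc("2024-03-01 08:00:00"),
                           outcomes = NULL) {
  times <- seq(arrival, arrival + los_hours * 3600, by = 60 * gap_minutes)
  events <- tibble::tibble(
    patient_id = id,
    timestamp = rep(times, 2),
    variable = rep(c("hr", "sbp"), each = length(times)),
    value = c(seq(80, 80 + length(times) - 1), rep(120, length(times))))
  t_arr <- arrival
  t_dep <- arrival + los_hours * 3600
  static <- tibble::tibble(patient_id = id, age = 50, sex = "female",
                           arrival = "other", t_arrival = t_arr,
                           t_departure = t_dep)
  make_cohort(events, static, outcomes)
}

# Random single-patient event stream for oracle-equivalence trials.
random_events <- function(n_events, arrival, los_hours,
                          features = feature_set("full")) {
  tibble::tibble(
    patient_id = "R",
    timestamp = arrival + round(runif(n_events, 0, los_hours * 3600)),
    variable = sample(features$variable, n_events, replace = TRUE),
    value = round(runif(n_events), 3))
}

# Tiny trained model fixture shared across model/explain tests (cached).
.tiny_env <- new.env(parent = emptyenv())

tiny_trained_model <- function() {
  if (!is.null(.tiny_env$fit)) return(.tiny_env$fit)
  vars <- default_variables()
  drift <- deterioration_spec(
    lead_time_hours = 12,
    magnitude = stats::setNames(ifelse(vars$variable == "hr", 2, 0),
                                vars$variable))
  spec <- cohort_spec(400, prevalence = 0.15, drift = drift, seed = 401)
  cohort <- generate_cohort(spec)
  split <- split_cohort(cohort, seed = 402)
  windows <- build_windows(cohort, feature_set("vitals_only"),
                           cadence_minutes = 60)
  cfg <- model_config(n_features = 6, static_dim = 3, d_model = 16L,
                      n_layers = 2L, d_ff = 32L, t_steps = 192L,
                      d_static = 4L, batch_size = 128L, epochs = 6L,
                      loss_weights = "auto", seed = 403)
  ids <- select_train_windows(
    windows, "icu_admission",
    split$patient_id[split$partition == "train"], 2L, 404L)
  fit <- train_tews(windows, "icu_admission", cfg, split,
                    train_window_ids = ids)
  .tiny_env$fit <- list(cohort = cohort, split = split, windows = windows,
                        config = cfg, model = fit)
  .tiny_env$fit
}
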
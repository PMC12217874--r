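# Synthetic ED cohort simulator. Generates event streams (timestamped vital
# signs and labs), static features and adverse-event outcomes whose marginal
# structure matches the group-conditional first-measurement summaries the
# pipeline was developed against, plus a pre-event deterioration drift that
# makes the 24-h-ahead label learnable.

#' Deterioration drift specification
#'
#' Describes the within-stay deterioration signal carried by adverse-event
#' patients: a monotone linear ramp that starts `lead_time_hours` before the
#' (first) adverse event, reaches `magnitude` standard deviations at the event
#' time and plateaus thereafter. Drift is exactly zero earlier than
#' `event_time - lead_time_hours`.
#'
#' @param lead_time_hours Hours before the event at which drift begins (> 0).
#' @param magnitude Named numeric vector of signed drift sizes in SD units at
#'   the event time, named by variable. Defaults: SBP -1.5, HR +1.5, RR +1.5,
#'   SpO2 -1.5, lactate +2.0, all others 0.
#' @param shape Ramp shape; only `"ramp"` (linear) is provided.
#' @return A `tews_drift` list.
#' @export
deterioration_spec <- function(lead_time_hours = 12,
                               magnitude = NULL,
                               shape = "ramp") {
  if (!is.numeric(lead_time_hours) || lead_time_hours <= 0) {
    stop("invalid deterioration spec: `lead_time_hours` must be > 0",
         call. = FALSE)
  }
  shape <- match.arg(shape, "ramp")
  if (is.null(magnitude)) {
    vars <- default_variables()
    magnitude <- stats::setNames(vars$drift_sd, vars$variable)
  }
  if (is.null(names(magnitude)) || any(!nzchar(names(magnitude)))) {
    stop("invalid deterioration spec: `magnitude` must be a named vector",
         call. = FALSE)
  }
  structure(list(lead_time_hours = lead_time_hours,
                 magnitude = magnitude, shape = shape),
            class = "tews_drift")
}

#' Cohort specification
#'
#' Parameters of the synthetic ED cohort generator. Defaults reproduce the
#' development population: 3.7% of patients experience at least one adverse
#' event; the mix over the five event types is proportional to the published
#' counts (vasopressor 6304, respiratory support 5017, ICU admission 8492,
#' septic shock 4124, cardiac arrest 548; a patient may hold several types);
#' group-conditional first measurements follow the published means/SDs; length
#' of stay is log-normal with a 6-hour median, capped at 72 h; vitals recur
#' every 30-60 min, labs are drawn 0-2 times per stay.
#'
#' @param n_patients Number of ED visits to simulate (positive integer).
#' @param prevalence Probability of at least one adverse event per patient,
#'   in `[0, 1)`. The default 0.037 matches the development population.
#' @param outcome_mix Probability distribution of the *primary* event type
#'   over the five types (must sum to 1). Secondary types are added so that the
#'   marginal share of each type among adverse-event patients matches the
#'   published shares (40.7/32.4/54.9/26.6/3.5%).
#' @param los_median_hours,los_sdlog,los_cap_hours Log-normal length-of-stay
#'   distribution (median, log-SD) and cap.
#' @param variables Variable table (see [default_variables()]): per-variable,
#'   per-group first-measurement mean/SD and valid range.
#' @param vitals_gap_minutes Length-2 range of the uniform inter-measurement
#'   gap for vital signs, in minutes.
#' @param lab_draw_probs Probabilities of 0, 1 or 2 draws per stay for each
#'   laboratory variable.
#' @param noise_sd Within-stay measurement noise, as a fraction of the group
#'   SD; measurements after the first follow an AR(1) mean-reverting walk
#'   around the first-measurement baseline.
#' @param ar_rho AR(1) coefficient of the within-stay walk.
#' @param drift A [deterioration_spec()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return A `tews_cohort_spec` list.
#' @export
#' @examples
#' spec <- cohort_spec(100, seed = 1)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_patients,
                        prevalence = 0.037,
                        outcome_mix = NULL,
                        los_median_hours = 6,
                        los_sdlog = 0.8,
                        los_cap_hours = 72,
                        variables = default_variables(),
                        vitals_gap_minutes = c(30, 60),
                        lab_draw_probs = c(0.2, 0.4, 0.4),
                        noise_sd = 0.3,
                        ar_rho = 0.8,
                        drift = deterioration_spec(),
                        seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      n_patients < 1 || n_patients != round(n_patients)) {
    stop("invalid cohort spec: `n_patients` must be a positive integer",
         call. = FALSE)
  }
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence >= 1) {
    stop("invalid cohort spec: `prevalence` must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(outcome_mix)) {
    counts <- c(vasopressor = 6304, respiratory_support = 5017,
                icu_admission = 8492, septic_shock = 4124,
                cardiac_arrest = 548)
    outcome_mix <- counts / sum(counts)
  }
  if (!setequal(names(outcome_mix), AE_TYPES) ||
      abs(sum(outcome_mix) - 1) > 1e-8 || any(outcome_mix < 0)) {
    stop("invalid cohort spec: `outcome_mix` must be a distribution over the ",
         "five event types summing to 1", call. = FALSE)
  }
  if (any(variables$ae_sd <= 0) || any(variables$nonae_sd <= 0)) {
    stop("invalid cohort spec: `variables` must have positive SDs",
         call. = FALSE)
  }
  if (any(variables$lo >= variables$hi)) {
    stop("invalid cohort spec: `variables` must satisfy lo < hi",
         call. = FALSE)
  }
  if (!inherits(drift, "tews_drift")) {
    stop("invalid cohort spec: `drift` must be a deterioration_spec()",
         call. = FALSE)
  }
  if (length(vitals_gap_minutes) != 2 || any(vitals_gap_minutes <= 0) ||
      vitals_gap_minutes[1] > vitals_gap_minutes[2]) {
    stop("invalid cohort spec: `vitals_gap_minutes` must be an increasing ",
         "positive range", call. = FALSE)
  }
  if (length(lab_draw_probs) != 3 || abs(sum(lab_draw_probs) - 1) > 1e-8) {
    stop("invalid cohort spec: `lab_draw_probs` must be 3 probabilities ",
         "summing to 1", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    outcome_mix = outcome_mix[AE_TYPES],
    los_median_hours = los_median_hours, los_sdlog = los_sdlog,
    los_cap_hours = los_cap_hours, variables = variables,
    vitals_gap_minutes = vitals_gap_minutes, lab_draw_probs = lab_draw_probs,
    noise_sd = noise_sd, ar_rho = ar_rho, drift = drift,
    seed = as.integer(seed)
  ), class = "tews_cohort_spec")
}

# Published marginal shares of each event type among adverse-event patients.
ae_marginal_shares <- c(vasopressor = 0.407, respiratory_support = 0.324,
                        icu_admission = 0.549, septic_shock = 0.266,
                        cardiac_arrest = 0.035)

# Draw n first-measurement values with exact mean/SD inside [lo, hi].
# Gaussian when both bounds are >= 3 SD away (clamping bias is then
# negligible); otherwise a moment-matched shifted gamma anchored at the
# nearest bound (mirrored for upper bounds, e.g. SpO2), which preserves the
# target mean/SD exactly while respecting the physiological range.
draw_first_values <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  d_lo <- (mean - lo) / sd
  d_hi <- (hi - mean) / sd
  if (min(d_lo, d_hi) >= 3) {
    x <- stats::rnorm(n, mean, sd)
  } else if (d_lo <= d_hi) {
    shape <- d_lo^2
    x <- lo + stats::rgamma(n, shape = shape, scale = sd^2 / (mean - lo))
  } else {
    shape <- d_hi^2
    x <- hi - stats::rgamma(n, shape = shape, scale = sd^2 / (hi - mean))
  }
  pmin(pmax(x, lo), hi)
}

# Linear drift ramp: 0 before (event - lead), 1 at the event, plateau after.
drift_ramp <- function(t_sec, event_sec, lead_sec) {
  pmin(pmax((t_sec - (event_sec - lead_sec)) / lead_sec, 0), 1)
}

# AR(1) recursion e_j = rho * e_{j-1} + eta_j with e_1 = 0, computed over a
# long vector of patient-major blocks (lengths `cap`) without a per-patient
# loop: iterate over the measurement index, addressing block starts sorted by
# block length so each pass is a single vectorised update.
ar1_by_block <- function(eta, cap, rho) {
  e <- numeric(length(eta))
  if (length(eta) == 0 || max(cap) < 2) return(e)
  starts <- cumsum(cap) - cap + 1
  ord <- order(cap, decreasing = TRUE)
  starts_sorted <- starts[ord]
  cap_sorted <- cap[ord]
  maxcap <- cap_sorted[1]
  n_ge <- length(cap) - findInterval(seq_len(maxcap) - 0.5, sort(cap))
  for (j in 2:maxcap) {
    sel <- starts_sorted[seq_len(n_ge[j])] + (j - 1)
    e[sel] <- rho * e[sel - 1] + eta[sel]
  }
  e
}

#' Generate a synthetic ED cohort
#'
#' Simulates `spec$n_patients` ED visits: static features (age, sex, mode of
#' arrival), irregular timestamped measurement events for every variable in
#' `spec$variables`, and adverse-event outcomes with event times. Adverse-event
#' patients carry a deterioration drift ending at their first event time; the
#' first measurement of every variable is drawn exactly from the
#' group-conditional distribution (the group baselines already encode
#' pre-arrival deterioration), and later measurements follow an AR(1)
#' mean-reverting walk around that baseline plus the drift, clamped to the
#' variable's valid range.
#'
#' @param spec A [cohort_spec()].
#' @return A `tews_cohort`: list of three tibbles, `events`
#'   (`patient_id`, `timestamp`, `variable`, `value`), `static` (`patient_id`,
#'   `age`, `sex`, `arrival`, `t_arrival`, `t_departure`) and `outcomes`
#'   (`patient_id`, `event_type`, `timestamp`). Deterministic given the spec.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(50, seed = 42))
#' dplyr::count(cohort$events, variable)
generate_cohort <- function(spec) {
  if (!inherits(spec, "tews_cohort_spec")) {
    stop("`spec` must be a cohort_spec()", call. = FALSE)
  }
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  vars <- spec$variables
  origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

  patient_id <- sprintf("P%07d", seq_len(n))
  ae <- stats::runif(n) < spec$prevalence

  # Statics: group-conditional age, sex, mode of arrival.
  age <- ifelse(ae, stats::rnorm(n, 65.0, 14.7), stats::rnorm(n, 55.3, 17.7))
  age <- round(pmin(pmax(age, 19), 110), 1)
  sex <- ifelse(stats::runif(n) < ifelse(ae, 0.616, 0.483),
                "female", "male")
  arrival <- ifelse(stats::runif(n) < ifelse(ae, 0.542, 0.177),
                    "ambulance", "other")
  t_arrival <- origin + round(stats::runif(n, 0, 365 * 86400))
  los_sec <- round(3600 * pmin(
    stats::rlnorm(n, log(spec$los_median_hours), spec$los_sdlog),
    spec$los_cap_hours))
  los_sec <- pmax(los_sec, 900)  # at least one 15-min bin of stay

  # Outcomes: primary type from outcome_mix, secondary types added so the
  # marginal share of each type among AE patients matches the published
  # shares; the primary event is the earliest (drift anchor).
  ae_idx <- which(ae)
  m <- length(ae_idx)
  event_sec <- rep(NA_real_, n)
  outcomes <- tibble::tibble(patient_id = character(0),
                             event_type = character(0),
                             timestamp = origin[0])
  if (m > 0) {
    primary <- sample(AE_TYPES, m, replace = TRUE, prob = spec$outcome_mix)
    t_primary <- round(los_sec[ae_idx] * stats::runif(m, 0.30, 0.95))
    event_sec[ae_idx] <- t_primary
    share <- ae_marginal_shares
    p_primary <- spec$outcome_mix
    extra_p <- pmax((share - p_primary) / pmax(1 - p_primary, 1e-12), 0)
    out_list <- list(tibble::tibble(
      patient_id = patient_id[ae_idx], event_type = primary,
      t_sec = t_primary))
    for (ty in AE_TYPES) {
      extra <- stats::runif(m) < extra_p[[ty]] & primary != ty
      if (any(extra)) {
        slack <- pmax(los_sec[ae_idx][extra] - t_primary[extra], 0)
        out_list[[length(out_list) + 1]] <- tibble::tibble(
          patient_id = patient_id[ae_idx][extra], event_type = ty,
          t_sec = t_primary[extra] + round(stats::runif(sum(extra)) *
                                             pmin(slack, 7200)))
      }
    }
    outcomes <- dplyr::bind_rows(out_list)
    oc_idx <- match(outcomes$patient_id, patient_id)
    outcomes <- tibble::tibble(
      patient_id = outcomes$patient_id, event_type = outcomes$event_type,
      timestamp = t_arrival[oc_idx] + outcomes$t_sec)
    outcomes <- dplyr::arrange(outcomes, .data$patient_id, .data$timestamp,
                               .data$event_type)
  }

  # First-measurement baselines, group-conditional per variable.
  nv <- nrow(vars)
  baseline <- matrix(NA_real_, n, nv, dimnames = list(NULL, vars$variable))
  for (v in seq_len(nv)) {
    b <- numeric(n)
    if (m > 0) {
      b[ae_idx] <- draw_first_values(m, vars$ae_mean[v], vars$ae_sd[v],
                                     vars$lo[v], vars$hi[v])
    }
    if (m < n) {
      b[!ae] <- draw_first_values(n - m, vars$nonae_mean[v], vars$nonae_sd[v],
                                  vars$lo[v], vars$hi[v])
    }
    baseline[, v] <- b
  }
  group_sd <- ifelse(ae, 1, 0) %o% vars$ae_sd + ifelse(ae, 0, 1) %o% vars$nonae_sd
  colnames(group_sd) <- vars$variable

  lead_sec <- spec$drift$lead_time_hours * 3600
  drift_mag <- spec$drift$magnitude
  los_min <- los_sec / 60

  event_tbls <- vector("list", nv)
  for (v in seq_len(nv)) {
    vn <- vars$variable[v]
    mag <- (drift_mag[vn] %||% 0) * vars$ae_sd[v]
    if (is.na(mag)) mag <- 0
    if (vars$role[v] == "vital") {
      gap_lo <- spec$vitals_gap_minutes[1]
      gap_hi <- spec$vitals_gap_minutes[2]
      cap <- pmax(1L, 1L + as.integer(los_min %/% gap_lo))
      total <- sum(cap)
      pid_i <- rep.int(seq_len(n), cap)
      j <- sequence(cap)
      gaps <- stats::runif(total, gap_lo, gap_hi)
      gaps[j == 1] <- 0
      cs <- cumsum(gaps)
      block_start <- cumsum(cap) - cap + 1
      t_min <- cs - rep.int(cs[block_start], cap)
      keep <- t_min <= los_min[pid_i]
      eta <- stats::rnorm(total, 0, spec$noise_sd) *
        group_sd[pid_i, v]
      e <- ar1_by_block(eta, cap, spec$ar_rho)
      t_sec <- round(t_min * 60)
      d <- numeric(total)
      has_ev <- !is.na(event_sec[pid_i])
      if (mag != 0 && any(has_ev)) {
        d[has_ev] <- mag * drift_ramp(t_sec[has_ev],
                                      event_sec[pid_i[has_ev]], lead_sec)
      }
      val <- baseline[cbind(pid_i, v)] + e + d
      val[j == 1] <- baseline[cbind(pid_i[j == 1], v)]
      event_tbls[[v]] <- tibble::tibble(
        pid = pid_i[keep], t_sec = t_sec[keep],
        variable = vn,
        value = round(pmin(pmax(val[keep], vars$lo[v]), vars$hi[v]), 2))
    } else {
      n_draws <- sample(0:2, n, replace = TRUE, prob = spec$lab_draw_probs)
      has1 <- n_draws >= 1
      t1 <- pmin(round(stats::runif(n, 10, 60) * 60), los_sec)
      has2 <- n_draws >= 2
      t2 <- round(los_sec * stats::runif(n, 0.35, 0.95))
      t2 <- pmax(t2, t1 + 1800)          # second draw at least 30 min later
      has2 <- has2 & t2 <= los_sec
      v1 <- baseline[, v]
      eta2 <- stats::rnorm(n, 0, spec$noise_sd) * group_sd[, v]
      d2 <- numeric(n)
      hv <- !is.na(event_sec)
      if (mag != 0 && any(hv)) {
        d2[hv] <- mag * drift_ramp(t2[hv], event_sec[hv], lead_sec)
      }
      v2 <- baseline[, v] + eta2 + d2
      event_tbls[[v]] <- tibble::tibble(
        pid = c(which(has1), which(has2)),
        t_sec = c(t1[has1], t2[has2]),
        variable = vn,
        value = round(pmin(pmax(c(v1[has1], v2[has2]), vars$lo[v]),
                           vars$hi[v]), 2))
    }
  }
  events <- dplyr::bind_rows(event_tbls)
  events <- tibble::tibble(
    patient_id = patient_id[events$pid],
    timestamp = t_arrival[events$pid] + events$t_sec,
    variable = events$variable,
    value = events$value)
  events <- dplyr::arrange(events, .data$patient_id, .data$variable,
                           .data$timestamp)

  static <- tibble::tibble(
    patient_id = patient_id, age = age, sex = sex, arrival = arrival,
    t_arrival = t_arrival, t_departure = t_arrival + los_sec)

  new_tews_cohort(events, static, outcomes, spec)
}

new_tews_cohort <- function(events, static, outcomes, spec = NULL) {
  structure(list(events = events, static = static, outcomes = outcomes),
            spec = spec, class = "tews_cohort")
}

#' @export
print.tews_cohort <- function(x, ...) {
  n_ae <- length(unique(x$outcomes$patient_id))
  cat("<tews_cohort> ", nrow(x$static), " patients, ",
      nrow(x$events), " events, ", n_ae, " with adverse events (",
      sprintf("%.2f%%", 100 * n_ae / max(nrow(x$static), 1)), ")\n", sep = "")
  invisible(x)
}

#' Patient-level train/validation/test split
#'
#' Partitions patients into train/validation/test sets sized by
#' largest-remainder rounding of the requested ratios; every patient lands in
#' exactly one partition, so no patient contributes windows to two partitions.
#'
#' @param cohort A `tews_cohort`, or a character vector of patient ids.
#' @param ratios Length-3 numeric summing to 1 (default 0.6/0.2/0.2).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Tibble with `patient_id` and `partition`
#'   (factor: train/validation/test).
#' @export
#' @examples
#' split_cohort(sprintf("P%03d", 1:5), seed = 1)
split_cohort <- function(cohort, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  ids <- if (inherits(cohort, "tews_cohort")) cohort$static$patient_id
         else as.character(cohort)
  if (length(ids) == 0) stop("cohort is empty", call. = FALSE)
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8 || any(ratios < 0)) {
    stop("invalid split: `ratios` must be 3 nonnegative numbers summing to 1",
         call. = FALSE)
  }
  n <- length(ids)
  q <- n * ratios
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- q - sizes
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  part <- rep(c("train", "validation", "test"), times = sizes)
  tibble::tibble(
    patient_id = shuffled,
    partition = factor(part, levels = c("train", "validation", "test"))
  ) |> dplyr::arrange(.data$patient_id)
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `events.csv`, `static.csv` and `outcomes.csv`
#' (timestamps in ISO-8601 at 1-second resolution) into `path`;
#' `read_cohort()` reads them back. The round trip is an identity:
#' `read_cohort(write_cohort(x, p))` equals `x` field for field.
#'
#' @param cohort A `tews_cohort`.
#' @param path Directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns a
#'   `tews_cohort`. Malformed numeric or timestamp fields raise a parse error
#'   naming the offending file and row.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tews_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(
    dplyr::mutate(cohort$events, timestamp = fmt(.data$timestamp)),
    file.path(path, "events.csv"))
  readr::write_csv(
    dplyr::mutate(cohort$static, t_arrival = fmt(.data$t_arrival),
                  t_departure = fmt(.data$t_departure)),
    file.path(path, "static.csv"))
  readr::write_csv(
    dplyr::mutate(cohort$outcomes, timestamp = fmt(.data$timestamp)),
    file.path(path, "outcomes.csv"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read_checked <- function(file, col_types) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("missing cohort file: ", f, call. = FALSE)
    x <- withCallingHandlers(
      readr::read_csv(f, col_types = col_types, progress = FALSE),
      warning = function(w) {
        if (inherits(w, "vroom_parse_issue")) {
          invokeRestart("muffleWarning")
        }
      })
    probs <- readr::problems(x)
    if (nrow(probs) > 0) {
      stop("parse error in ", file, " at line(s) ",
           paste(utils::head(probs$row, 5), collapse = ", "),
           ": ", probs$expected[1], " expected, got '", probs$actual[1], "'",
           call. = FALSE)
    }
    x
  }
  ts_col <- readr::col_datetime(format = "%Y-%m-%dT%H:%M:%S")
  events <- read_checked("events.csv", readr::cols(
    patient_id = readr::col_character(), timestamp = ts_col,
    variable = readr::col_character(), value = readr::col_double()))
  static <- read_checked("static.csv", readr::cols(
    patient_id = readr::col_character(), age = readr::col_double(),
    sex = readr::col_character(), arrival = readr::col_character(),
    t_arrival = ts_col, t_departure = ts_col))
  outcomes <- read_checked("outcomes.csv", readr::cols(
    patient_id = readr::col_character(), event_type = readr::col_character(),
    timestamp = ts_col))
  new_tews_cohort(events, static, outcomes)
}
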
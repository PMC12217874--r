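# Preprocessing: event streams -> windowed model inputs.
#
# Conventions (enforced by oracle tests):
#   * a window ending at prediction time `end` spans [end - 48 h, end),
#     half-open, so a measurement exactly at the prediction time is excluded;
#   * bin t (1..192) covers [end - (193 - t)*15 min, end - (192 - t)*15 min);
#     within a bin the latest measurement per variable wins, ties broken by
#     input row order (later row wins);
#   * empty bins are imputed with 0 after min-max scaling, with a 0 mask;
#   * label horizon is half-open on the left: an adverse event at time e makes
#     the label 1 iff e is in (end, end + 24 h].

#' Remove physiologically impossible measurements
#'
#' Drops events whose value falls outside the variable's clinically acceptable
#' range `[lo, hi]` (closed interval: boundary values are retained). Values are
#' never modified, only dropped. The number of removals per variable is
#' attached as attribute `n_removed`.
#'
#' @param events Tibble with columns `variable`, `value` (plus any others).
#' @param variables Variable table with `variable`, `lo`, `hi`; every event's
#'   variable must appear in it.
#' @return The filtered events tibble, with attribute `n_removed` (a tibble of
#'   per-variable removal counts).
#' @export
#' @examples
#' ev <- tibble::tibble(variable = "sbp", value = c(120, 400))
#' filter_outliers(ev, default_variables())
filter_outliers <- function(events, variables) {
  idx <- variable_rows(variables, events$variable)
  ok <- events$value >= variables$lo[idx] & events$value <= variables$hi[idx]
  removed <- events$variable[!ok]
  out <- events[ok, , drop = FALSE]
  attr(out, "n_removed") <- tibble::tibble(
    variable = variables$variable,
    n_removed = as.integer(
      tabulate(match(removed, variables$variable), nrow(variables))))
  out
}

#' Min-max scale values to the unit interval
#'
#' Maps `value` to `(value - lo) / (hi - lo)` using the variable's fixed
#' clinical scaling range. Values outside the range (possible only if outlier
#' filtering was skipped) are clipped to `[0, 1]` with a warning.
#'
#' @param value Numeric vector.
#' @param lo,hi Scaling range (lo < hi).
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' scale_minmax(165, 30, 300)
scale_minmax <- function(value, lo, hi) {
  stopifnot(lo < hi)
  x <- (value - lo) / (hi - lo)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    warning("values outside the scaling range were clipped to [0, 1]",
            call. = FALSE)
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Resample one patient's events into a (192 x N) window
#'
#' Assigns each (already filtered and scaled) event to one of `t_steps`
#' `bin_minutes`-wide bins ending at `window_end`; within each bin the latest
#' value per variable wins; empty bins are 0 with mask 0.
#'
#' @param events Tibble for one patient: `timestamp`, `variable`, `value`
#'   (scaled to `[0, 1]`).
#' @param window_end POSIXct prediction time (window is `[end - T*bin, end)`).
#' @param features A [feature_set()] naming the variable columns, in order.
#' @param t_steps,bin_minutes Window geometry (defaults 192 x 15 min = 48 h).
#' @return List with `X` (t_steps x n_features matrix) and `mask`
#'   (same shape; 1 where a real measurement landed).
#' @export
resample_to_bins <- function(events, window_end, features,
                             t_steps = 192L, bin_minutes = 15) {
  nf <- nrow(features)
  X <- matrix(0, t_steps, nf, dimnames = list(NULL, features$variable))
  mask <- X
  if (nrow(events) == 0) return(list(X = X, mask = mask))
  feat <- match(events$variable, features$variable)
  delta <- as.numeric(difftime(window_end, events$timestamp, units = "mins"))
  keep <- !is.na(feat) & delta > 0 & delta <= t_steps * bin_minutes
  if (!any(keep)) return(list(X = X, mask = mask))
  ev <- events[keep, , drop = FALSE]
  feat <- feat[keep]
  bin <- t_steps - as.integer(ceiling(delta[keep] / bin_minutes)) + 1L
  ord <- order(feat, bin, ev$timestamp, seq_along(bin))
  last <- !duplicated(cbind(feat, bin)[ord, , drop = FALSE], fromLast = TRUE)
  sel <- ord[last]
  X[cbind(bin[sel], feat[sel])] <- ev$value[sel]
  mask[cbind(bin[sel], feat[sel])] <- 1
  list(X = X, mask = mask)
}

#' Encode static patient features
#'
#' Age is min-max scaled on `[19, 110]`; sex is coded female = 1, male = 0;
#' mode of arrival is coded ambulance = 1, other = 0 (included by default,
#' switch off with `include_arrival = FALSE`).
#'
#' @param static Tibble with `patient_id`, `age`, `sex`, `arrival`.
#' @param include_arrival Include the mode-of-arrival indicator?
#' @return Tibble with `patient_id` and numeric columns `age`, `sex`
#'   (and `arrival`); the static dimension k is `ncol - 1`.
#' @export
encode_static <- function(static, include_arrival = TRUE) {
  need <- c("age", "sex", if (include_arrival) "arrival")
  bad <- static$patient_id[!stats::complete.cases(static[, need])]
  if (length(bad) > 0) {
    stop("missing static features for patient(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(static$age < 19)) {
    stop("age below 19 for patient(s): ",
         paste(utils::head(static$patient_id[static$age < 19], 5),
               collapse = ", "), call. = FALSE)
  }
  rng <- tews_constants()$age_scale_range
  out <- tibble::tibble(
    patient_id = static$patient_id,
    age = pmin((static$age - rng[1]) / (rng[2] - rng[1]), 1),
    sex = as.numeric(static$sex == "female"))
  if (include_arrival) {
    out$arrival <- as.numeric(static$arrival == "ambulance")
  }
  out
}

#' Per-outcome 24-h-ahead labels for one prediction time
#'
#' The label for outcome `o` is 1 iff an event of that type occurs in
#' `(prediction_time, prediction_time + horizon]`.
#'
#' @param outcomes Tibble of one patient's adverse events
#'   (`event_type`, `timestamp`).
#' @param prediction_time POSIXct prediction time.
#' @param horizon_hours Label horizon (default 24).
#' @return Named integer vector over the five event types.
#' @export
assign_labels <- function(outcomes, prediction_time, horizon_hours = 24) {
  labs <- stats::setNames(integer(length(AE_TYPES)), AE_TYPES)
  if (nrow(outcomes) == 0) return(labs)
  dt <- as.numeric(difftime(outcomes$timestamp, prediction_time,
                            units = "hours"))
  hit <- outcomes$event_type[dt > 0 & dt <= horizon_hours]
  labs[unique(hit)] <- 1L
  labs
}

#' Build windowed model inputs from a cohort
#'
#' Runs the full preprocessing chain: restrict to the feature set, drop
#' outliers, min-max scale, enumerate prediction time points (every
#' `cadence_minutes` from each patient's first retained measurement to
#' departure), resample each window into the `(192, N)` representation, and
#' attach per-outcome labels and eligibility flags (windows at or after a
#' patient's own first event of an outcome are ineligible for that outcome:
#' the model predicts onset, not presence).
#'
#' @param cohort A `tews_cohort`.
#' @param features A [feature_set()].
#' @param cadence_minutes Spacing of prediction time points (default 15).
#' @param horizon_hours Label horizon (default 24).
#' @param window_hours Look-back window (default 48).
#' @param include_arrival Passed to [encode_static()].
#' @return A `tews_windows` object: `index` (one row per window: `window_id`,
#'   `patient_id`, `prediction_time`, `label_<type>`, `elig_<type>`), `values`
#'   (sparse non-zero entries: `window_id`, `bin`, `feature`, `value`),
#'   `statics` (encoded static features per patient) and metadata.
#' @export
build_windows <- function(cohort, features = feature_set("full"),
                          cadence_minutes = 15, horizon_hours = 24,
                          window_hours = 48, include_arrival = TRUE) {
  stopifnot(inherits(cohort, "tews_cohort"))
  t_steps <- as.integer(window_hours * 60 / tews_constants()$bin_minutes)
  bin_minutes <- tews_constants()$bin_minutes

  # outcome before arrival is a data-integrity failure
  if (nrow(cohort$outcomes) > 0) {
    arr <- cohort$static$t_arrival[
      match(cohort$outcomes$patient_id, cohort$static$patient_id)]
    bad <- cohort$outcomes$timestamp < arr
    if (any(bad)) {
      stop("adverse event before arrival for patient(s): ",
           paste(utils::head(unique(cohort$outcomes$patient_id[bad]), 5),
                 collapse = ", "), call. = FALSE)
    }
  }

  ev <- cohort$events[cohort$events$variable %in% features$variable, ,
                      drop = FALSE]
  ev <- filter_outliers(ev, features)
  n_removed <- attr(ev, "n_removed")
  fi <- variable_rows(features, ev$variable)
  ev$value <- (ev$value - features$lo[fi]) / (features$hi[fi] - features$lo[fi])
  ev$feature <- fi

  # prediction grid: every cadence_minutes from first retained measurement
  first_t <- dplyr::summarise(dplyr::group_by(ev, .data$patient_id),
                              t0 = min(.data$timestamp), .groups = "drop")
  first_t <- dplyr::left_join(
    first_t,
    cohort$static[, c("patient_id", "t_departure")], by = "patient_id")
  n_win <- pmax(0L, 1L + as.integer(floor(
    as.numeric(difftime(first_t$t_departure, first_t$t0, units = "mins")) /
      cadence_minutes)))
  index <- tibble::tibble(
    patient_id = rep.int(first_t$patient_id, n_win),
    prediction_time = rep(first_t$t0, n_win) +
      60 * cadence_minutes * (sequence(n_win) - 1))
  index$window_id <- seq_len(nrow(index))

  # sparse bin assignment: join events to windows of the same patient
  vals <- dplyr::inner_join(
    ev[, c("patient_id", "timestamp", "feature", "value")],
    index, by = "patient_id", relationship = "many-to-many")
  delta <- as.numeric(difftime(vals$prediction_time, vals$timestamp,
                               units = "mins"))
  keep <- delta > 0 & delta <= t_steps * bin_minutes
  vals <- vals[keep, , drop = FALSE]
  vals$bin <- t_steps - as.integer(ceiling(delta[keep] / bin_minutes)) + 1L
  # last-in-bin per (window, feature): order by time then input row
  key <- (vals$window_id * 16 + vals$feature) * 256 + vals$bin
  ord <- order(key, vals$timestamp, seq_along(key))
  vals <- vals[ord[!duplicated(key[ord], fromLast = TRUE)], , drop = FALSE]
  values <- tibble::tibble(window_id = vals$window_id, bin = vals$bin,
                           feature = vals$feature, value = vals$value)
  values <- dplyr::arrange(values, .data$window_id, .data$feature, .data$bin)

  # labels and eligibility per outcome
  for (ty in AE_TYPES) {
    index[[paste0("label_", ty)]] <- 0L
    index[[paste0("elig_", ty)]] <- TRUE
  }
  oc <- cohort$outcomes
  if (nrow(oc) > 0) {
    first_ev <- dplyr::summarise(
      dplyr::group_by(oc, .data$patient_id, .data$event_type),
      t_event = min(.data$timestamp), .groups = "drop")
    for (ty in AE_TYPES) {
      fe <- first_ev[first_ev$event_type == ty, , drop = FALSE]
      te <- fe$t_event[match(index$patient_id, fe$patient_id)]
      dt <- as.numeric(difftime(te, index$prediction_time, units = "hours"))
      index[[paste0("label_", ty)]] <-
        as.integer(!is.na(dt) & dt > 0 & dt <= horizon_hours)
      index[[paste0("elig_", ty)]] <- is.na(dt) | dt > 0
    }
  }
  index <- index[, c("window_id", "patient_id", "prediction_time",
                     paste0("label_", AE_TYPES), paste0("elig_", AE_TYPES))]

  statics <- encode_static(cohort$static, include_arrival = include_arrival)
  statics <- statics[statics$patient_id %in% index$patient_id, , drop = FALSE]

  structure(list(
    index = index, values = values, statics = statics, features = features,
    t_steps = t_steps, bin_minutes = bin_minutes,
    cadence_minutes = cadence_minutes, horizon_hours = horizon_hours,
    window_hours = window_hours, n_removed = n_removed,
    include_arrival = include_arrival
  ), class = "tews_windows")
}

#' @export
print.tews_windows <- function(x, ...) {
  cat("<tews_windows> ", nrow(x$index), " windows x (", x$t_steps, " x ",
      nrow(x$features), "), ", length(unique(x$index$patient_id)),
      " patients, feature set '", attr(x$features, "feature_set"), "'\n",
      sep = "")
  invisible(x)
}

#' Materialise windows as dense arrays
#'
#' Expands the sparse window representation into a dense `(T, N, B)` array
#' plus the aligned static matrix, e.g. for one training batch.
#'
#' @param windows A `tews_windows`.
#' @param window_ids Integer window ids (default: all).
#' @return List with `X` (T x N x B array), `mask` (same shape), `S`
#'   (B x k static matrix) and `first_bin` (earliest observed bin per window;
#'   T + 1 when the window is empty).
#' @export
window_tensor <- function(windows, window_ids = windows$index$window_id) {
  cache <- make_tensor_cache(windows)
  tensor_batch(cache, match(window_ids, cache$window_ids))
}

# Internal: precomputed sparse layout for fast repeated batch assembly.
make_tensor_cache <- function(windows) {
  idx <- windows$index
  v <- windows$values  # already sorted by window_id
  wid <- idx$window_id
  pos <- match(v$window_id, wid)
  len <- tabulate(pos, length(wid))
  start <- cumsum(len) - len + 1L
  smat <- as.matrix(windows$statics[
    match(idx$patient_id, windows$statics$patient_id),
    setdiff(names(windows$statics), "patient_id")])
  list(window_ids = wid, bin = v$bin, feature = v$feature, value = v$value,
       start = start, len = len, statics = smat,
       t_steps = windows$t_steps, n_features = nrow(windows$features))
}

tensor_batch <- function(cache, i) {
  b <- length(i)
  t_steps <- cache$t_steps
  nf <- cache$n_features
  X <- array(0, c(t_steps, nf, b))
  mask <- array(0, c(t_steps, nf, b))
  lens <- cache$len[i]
  rows <- sequence(lens, from = cache$start[i])
  if (length(rows) > 0) {
    slice <- rep.int(seq_len(b), lens)
    lin <- (slice - 1) * (t_steps * nf) +
      (cache$feature[rows] - 1) * t_steps + cache$bin[rows]
    X[lin] <- cache$value[rows]
    mask[lin] <- 1
  }
  first_bin <- rep(t_steps + 1L, b)
  if (length(rows) > 0) {
    fb <- tapply(cache$bin[rows], rep.int(seq_len(b), lens), min)
    first_bin[as.integer(names(fb))] <- as.integer(fb)
  }
  list(X = X, mask = mask, S = cache$statics[i, , drop = FALSE],
       first_bin = first_bin)
}
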
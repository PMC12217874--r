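# Modified Early Warning Score baseline, computed at the same prediction time
# points as the transformer model. Band table follows the standard published
# MEWS definition (systolic blood pressure, heart rate, respiratory rate,
# temperature, AVPU), shipped as a data file so variants can be dropped in.
#
# Conventions: missing components score 0 (the common operational convention);
# AVPU is not part of the modelled event stream, so it defaults to "alert"
# (0 points) but can be supplied.

#' MEWS band table
#'
#' Reads a band table mapping half-open value intervals `[lo, hi)` to points
#' per parameter. The default is the standard published MEWS: SBP (3/2/1/0/2),
#' HR (2/1/0/1/2/3), RR (2/0/1/2/3), temperature (2/0/2) and AVPU (0-3 for
#' alert/voice/pain/unresponsive), maximum total 14.
#'
#' @param path CSV file with columns `parameter`, `lo`, `hi`, `points`.
#' @return A `tews_mews_bands` tibble.
#' @export
#' @examples
#' mews_bands()
mews_bands <- function(path = system.file("extdata", "mews_bands.csv",
                                          package = "tewsr")) {
  bands <- readr::read_csv(path, col_types = readr::cols(
    parameter = readr::col_character(), lo = readr::col_double(),
    hi = readr::col_double(), points = readr::col_integer()),
    progress = FALSE)
  for (p in unique(bands$parameter)) {
    b <- dplyr::arrange(bands[bands$parameter == p, ], .data$lo)
    if (any(b$lo[-1] != b$hi[-nrow(b)])) {
      stop("MEWS bands for '", p, "' are overlapping or leave gaps",
           call. = FALSE)
    }
  }
  structure(bands, class = c("tews_mews_bands", class(bands)))
}

band_points <- function(value, parameter, bands) {
  b <- bands[bands$parameter == parameter, , drop = FALSE]
  b <- b[order(b$lo), , drop = FALSE]
  pts <- b$points[findInterval(value, c(b$lo[1], b$hi))]
  pts[is.na(value)] <- 0L
  as.integer(pts)
}

#' Modified Early Warning Score for one observation set
#'
#' Sums the band points of the latest systolic blood pressure, heart rate,
#' respiratory rate, temperature and AVPU status. Unobserved components (`NA`)
#' contribute 0 points.
#'
#' @param sbp,hr,rr,temp Numeric vectors (recycled to a common length) of raw
#'   (unscaled) values; `NA` = unobserved.
#' @param avpu AVPU status: `"alert"`, `"voice"`, `"pain"` or
#'   `"unresponsive"` (default `"alert"`).
#' @param bands Band table from [mews_bands()].
#' @return Integer score vector (0 to the table maximum).
#' @export
#' @examples
#' mews_score(sbp = 120, hr = 75, rr = 14, temp = 37)     # 0
#' mews_score(sbp = 65, hr = 135, rr = 32, temp = 34.2,
#'            avpu = "unresponsive")                      # 14
mews_score <- function(sbp = NA, hr = NA, rr = NA, temp = NA, avpu = "alert",
                       bands = mews_bands()) {
  n <- max(length(sbp), length(hr), length(rr), length(temp), length(avpu))
  avpu_num <- match(rep_len(avpu, n),
                    c("alert", "voice", "pain", "unresponsive")) - 1
  band_points(rep_len(sbp, n), "sbp", bands) +
    band_points(rep_len(hr, n), "hr", bands) +
    band_points(rep_len(rr, n), "rr", bands) +
    band_points(rep_len(temp, n), "temp", bands) +
    band_points(avpu_num, "avpu", bands)
}

#' MEWS series at given prediction time points
#'
#' Computes MEWS for each requested (patient, prediction time) pair using the
#' last observed raw value of each component strictly before the prediction
#' time and within the look-back window (same half-open convention as the
#' model windows), and an alarm indicator at `score >= threshold`.
#'
#' @param cohort A `tews_cohort` (raw, unscaled events).
#' @param at Tibble with `patient_id` and `prediction_time` (e.g. the `index`
#'   of a [build_windows()] result).
#' @param threshold Alarm threshold (default 5).
#' @param window_hours Look-back limit for carry-forward (default 48).
#' @param bands Band table from [mews_bands()].
#' @return `at` with `mews` (integer score) and `alarm` (0/1) appended.
#' @export
mews_series <- function(cohort, at, threshold = 5, window_hours = 48,
                        bands = mews_bands()) {
  stopifnot(all(c("patient_id", "prediction_time") %in% names(at)))
  comp <- c("sbp", "hr", "rr", "temp")
  ev <- cohort$events[cohort$events$variable %in% comp, , drop = FALSE]
  out <- at
  vals <- matrix(NA_real_, nrow(at), length(comp),
                 dimnames = list(NULL, comp))
  if (nrow(ev) > 0 && nrow(at) > 0) {
    at_key <- tibble::tibble(patient_id = at$patient_id,
                             prediction_time = at$prediction_time,
                             .row = seq_len(nrow(at)))
    joined <- dplyr::inner_join(ev, at_key, by = "patient_id",
                                relationship = "many-to-many")
    dt <- as.numeric(difftime(joined$prediction_time, joined$timestamp,
                              units = "hours"))
    joined <- joined[dt > 0 & dt <= window_hours, , drop = FALSE]
    if (nrow(joined) > 0) {
      # latest observation per (prediction row, component)
      ci <- match(joined$variable, comp)
      key <- joined$.row * length(comp) + ci
      ord <- order(key, joined$timestamp, seq_along(key))
      sel <- ord[!duplicated(key[ord], fromLast = TRUE)]
      vals[cbind(joined$.row[sel], ci[sel])] <- joined$value[sel]
    }
  }
  out$mews <- mews_score(vals[, "sbp"], vals[, "hr"], vals[, "rr"],
                         vals[, "temp"], bands = bands)
  out$alarm <- as.integer(out$mews >= threshold)
  out
}
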
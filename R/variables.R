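# Variable definitions: measurement roles, clinically acceptable ranges used
# for outlier filtering, scaling ranges, and the group-conditional
# first-measurement parameters (mean/SD in the adverse-event and no-event
# groups) that the cohort simulator reproduces.

#' Default variable table
#'
#' One row per modelled variable: role (`vital` or `lab`), the clinically
#' acceptable range `[lo, hi]` used to drop outliers (closed interval), and the
#' group-conditional first-measurement mean/SD for patients with and without an
#' adverse event. The scaling range for min-max normalisation equals the valid
#' range, so a scaled value of 0 is unambiguous and no fitted scaler needs to
#' be stored for external application.
#'
#' @return A tibble with columns `variable`, `role`, `lo`, `hi`, `ae_mean`,
#'   `ae_sd`, `nonae_mean`, `nonae_sd`, `drift_sd`.
#' @export
#' @examples
#' default_variables()
default_variables <- function() {
  tibble::tribble(
    ~variable,     ~role,   ~lo,  ~hi,  ~ae_mean, ~ae_sd, ~nonae_mean, ~nonae_sd, ~drift_sd,
    "sbp",         "vital",  30,  300,  122.0,    34.8,   132.4,       24.6,      -1.5,
    "dbp",         "vital",  10,  200,   71.6,    21.3,    79.8,       15.3,       0.0,
    "hr",          "vital",  10,  300,  101.3,    28.2,    88.9,       19.3,       1.5,
    "rr",          "vital",   4,   60,   21.3,     6.0,    18.5,        3.2,       1.5,
    "temp",        "vital",  30,   43,   37.1,     1.2,    36.9,        0.8,       0.0,
    "spo2",        "vital",  50,  100,   93.9,     9.1,    97.6,        4.3,      -1.5,
    "hb",          "lab",     2,   25,   11.4,     2.8,    12.5,        2.4,       0.0,
    "bun",         "lab",     1,  300,   29.4,    23.9,    18.0,       16.3,       0.0,
    "sodium",      "lab",   100,  185,  134.6,     6.9,   137.7,        4.7,       0.0,
    "potassium",   "lab",     1,   12,    4.4,     1.2,     4.2,        0.6,       0.0,
    "lactate",     "lab",   0.1,   30,    3.6,     3.8,     1.7,        1.2,       2.0,
    "ph",          "lab",   6.5,  8.0,    7.4,     0.2,     7.4,        0.1,       0.0,
    "bicarbonate", "lab",     2,   60,   20.9,     6.7,    23.2,        4.5,       0.0
  )
}

#' Feature sets
#'
#' The full model uses 13 variables (six vital signs and seven laboratory
#' values); the vital-sign-only model uses the first six.
#'
#' @param name `"full"` (13 variables) or `"vitals_only"` (6 vital signs).
#' @param variables Variable table, as from [default_variables()].
#' @return A `tews_features` object: the variable table subset, with the
#'   feature-set name attached.
#' @export
#' @examples
#' feature_set("vitals_only")$variable
feature_set <- function(name = c("full", "vitals_only"),
                        variables = default_variables()) {
  name <- match.arg(name)
  vars <- if (name == "full") variables else
    dplyr::filter(variables, .data$role == "vital")
  structure(vars, feature_set = name, class = c("tews_features", class(vars)))
}

#' @export
print.tews_features <- function(x, ...) {
  cat("<tews_features> ", attr(x, "feature_set"), " (", nrow(x),
      " variables)\n", sep = "")
  NextMethod()
}

# Internal: look up rows of a variable table by name, erroring on unknowns.
variable_rows <- function(variables, names) {
  idx <- match(names, variables$variable)
  if (anyNA(idx)) {
    stop("unknown variable(s): ",
         paste(unique(names[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  idx
}
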
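# Central constants of the TEWS pipeline. Every tunable that the method fixes
# lives here so that configuration files, tests and documentation agree on a
# single source of truth.

#' Pipeline constants
#'
#' Returns the fixed constants of the TEWS method as a named list:
#' window geometry (48 h window, 15-min bins, 192 time steps), the 24-h label
#' horizon, the 60/20/20 patient-level split, the published model
#' configuration (4 encoder layers, single-head attention, hidden size 512,
#' AdamW at learning rate 1e-4, batch size 1000, 200 epochs), the published
#' class weights (5.495, 0.505), the MEWS alarm threshold (>= 5), the risk-tier
#' anchors (90% sensitivity, 95% specificity), the bootstrap resample count
#' (1000) and the transfer-learning fractions (1%, 5%).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' tews_constants()$t_steps
tews_constants <- function() {
  list(
    window_hours     = 48,
    bin_minutes      = 15,
    t_steps          = 192L,   # 48 h / 15 min
    horizon_hours    = 24,
    split_ratios     = c(train = 0.6, validation = 0.2, test = 0.2),
    n_layers         = 4L,
    n_heads          = 1L,
    d_model          = 512L,
    learning_rate    = 1e-4,
    batch_size       = 1000L,
    epochs           = 200L,
    loss_weights     = c(pos = 5.495, neg = 0.505),
    prevalence       = 0.037,
    mews_threshold   = 5L,
    tier_sensitivity = 0.90,
    tier_specificity = 0.95,
    n_boot           = 1000L,
    transfer_fractions = c(0.01, 0.05),
    age_scale_range  = c(19, 110),
    prob_eps         = 1e-7   # probability clamp inside the weighted BCE
  )
}

# Adverse-event types, in the fixed order used throughout the package.
AE_TYPES <- c("vasopressor", "respiratory_support", "icu_admission",
              "septic_shock", "cardiac_arrest")

`%||%` <- function(a, b) if (is.null(a)) b else a
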
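# Evaluation: discrimination metrics, Youden and matched-sensitivity
# thresholds, risk tiers, false alarms per 1,000 patients, and patient-level
# bootstrap uncertainty.
#
# The primary evaluation unit is the patient visit: each visit is scored by
# the maximum of its window scores (alarm semantics) and labelled 1 if any of
# its eligible windows is labelled 1. The alarm rule is `score >= threshold`
# throughout, consistent with "MEWS >= 5".

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability with ties counted 1/2, computed from
#' rank sums.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC is undefined with a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) interpolation over recall, summing
#' `precision * (recall step)` at each distinct score threshold in descending
#' order; with uninformative constant scores the value equals the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPRC is undefined without positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

# Threshold sweep over the observed score values: sensitivity and specificity
# of the alarm rule score >= t for each candidate t.
threshold_sweep <- function(scores, labels) {
  thr <- sort(unique(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  # counts of scores >= t via cumulative sums over the sorted unique grid
  pos_tab <- rev(cumsum(rev(tabulate(match(scores[labels == 1], thr),
                                     length(thr)))))
  neg_tab <- rev(cumsum(rev(tabulate(match(scores[labels == 0], thr),
                                     length(thr)))))
  tibble::tibble(threshold = thr,
                 sensitivity = if (n_pos > 0) pos_tab / n_pos else NA_real_,
                 specificity = if (n_neg > 0) 1 - neg_tab / n_neg
                               else NA_real_)
}

#' Youden-index optimal threshold
#'
#' The observed score value maximising sensitivity + specificity - 1; ties are
#' broken toward the lowest threshold (favouring sensitivity).
#'
#' @inheritParams auroc
#' @return Threshold on the score scale.
#' @export
#' @examples
#' youden_cutoff(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.7
youden_cutoff <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop("Youden threshold is undefined with a single class", call. = FALSE)
  }
  sw <- threshold_sweep(scores, labels)
  j <- sw$sensitivity + sw$specificity - 1
  # ties (within floating-point noise) break toward the lowest threshold
  sw$threshold[which(j >= max(j) - 1e-9)[1]]
}

#' Confusion-matrix metrics at a threshold
#'
#' Alarm iff `score >= threshold`. False alarms per 1,000 patients are
#' `1000 * FP / N` over all evaluated units.
#'
#' @inheritParams auroc
#' @param threshold Alarm threshold (finite).
#' @return One-row tibble: sensitivity, specificity, ppv, npv,
#'   false_alarms_per_1000, threshold, tp/fp/tn/fn counts.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  alarm <- scores >= threshold
  tp <- sum(alarm & labels == 1)
  fp <- sum(alarm & labels == 0)
  tn <- sum(!alarm & labels == 0)
  fn <- sum(!alarm & labels == 1)
  tibble::tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    false_alarms_per_1000 = 1000 * fp / length(labels),
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Threshold matching a reference sensitivity
#'
#' The largest threshold whose sensitivity is at least `reference_sensitivity`
#' (the achievable sensitivity closest to the reference from above), used to
#' compare scorers at a common sensitivity level.
#'
#' @inheritParams auroc
#' @param reference_sensitivity Target sensitivity in (0, 1].
#' @return Threshold, with attribute `achieved_sensitivity`.
#' @export
matched_sensitivity_threshold <- function(scores, labels,
                                          reference_sensitivity) {
  if (!is.numeric(reference_sensitivity) || reference_sensitivity <= 0 ||
      reference_sensitivity > 1) {
    stop("`reference_sensitivity` must lie in (0, 1]", call. = FALSE)
  }
  sw <- threshold_sweep(scores, labels)
  ok <- which(sw$sensitivity >= reference_sensitivity)
  if (length(ok) == 0) {
    stop("no threshold reaches sensitivity ", reference_sensitivity,
         call. = FALSE)
  }
  i <- max(ok)  # thresholds ascend; sensitivity is non-increasing
  structure(sw$threshold[i], achieved_sensitivity = sw$sensitivity[i])
}

#' Risk-tier cutpoints
#'
#' `low_cut` is the threshold anchored at `sens_target` sensitivity (the
#' largest threshold whose sensitivity still reaches the target: scores below
#' it are low risk); `high_cut` is anchored at `spec_target` specificity (the
#' smallest threshold at or above `low_cut` whose specificity reaches the
#' target: scores at or above it are high risk), so `low_cut <= high_cut`
#' always holds and the intermediate tier may be empty. If no threshold at or
#' above `low_cut` reaches the specificity target (e.g. constant scores), the
#' cutpoints collapse with a warning.
#'
#' @inheritParams auroc
#' @param sens_target,spec_target Tier anchors (defaults 0.90 and 0.95).
#' @return List: `low_cut`, `high_cut`, achieved sensitivity/specificity.
#' @export
risk_tiers <- function(scores, labels, sens_target = 0.90,
                       spec_target = 0.95) {
  if (length(unique(labels)) < 2) {
    stop("risk tiers are undefined with a single class", call. = FALSE)
  }
  sw <- threshold_sweep(scores, labels)
  ok_s <- which(sw$sensitivity >= sens_target)
  low_i <- if (length(ok_s) > 0) max(ok_s) else 1L
  ok_p <- which(sw$specificity >= spec_target & seq_len(nrow(sw)) >= low_i)
  if (length(ok_p) > 0) {
    high_i <- min(ok_p)
  } else {
    warning("no threshold at or above the sensitivity anchor reaches the ",
            "specificity target; tiers collapse to a single cutpoint",
            call. = FALSE)
    high_i <- low_i
  }
  list(low_cut = sw$threshold[low_i], high_cut = sw$threshold[high_i],
       achieved_sensitivity = sw$sensitivity[low_i],
       achieved_specificity = sw$specificity[high_i])
}

#' Assign risk tiers from cutpoints
#'
#' @param scores Numeric scores.
#' @param tiers A [risk_tiers()] result.
#' @return Factor with levels low/intermediate/high: low below `low_cut`,
#'   high at or above `high_cut`.
#' @export
assign_risk_tiers <- function(scores, tiers) {
  tier <- ifelse(scores >= tiers$high_cut, "high",
                 ifelse(scores >= tiers$low_cut, "intermediate", "low"))
  factor(tier, levels = c("low", "intermediate", "high"))
}

#' Aggregate window scores to patient visits
#'
#' Visit score = maximum window score; visit label = 1 if any window labelled.
#'
#' @param pred Tibble with `patient_id`, `label` and a score column.
#' @param score_col Name of the score column (default `.pred`).
#' @return Tibble `patient_id`, `score`, `label` (one row per visit).
#' @export
aggregate_visits <- function(pred, score_col = ".pred") {
  dplyr::summarise(dplyr::group_by(pred, .data$patient_id),
                   score = max(.data[[score_col]]),
                   label = max(.data$label), .groups = "drop")
}

# Patient-level bootstrap machinery: resample visits with replacement (all of
# a visit's rows come along), recompute a statistic per resample.
boot_indices <- function(patient_id) {
  ids <- unique(patient_id)
  rows_by_id <- split(seq_along(patient_id), factor(patient_id, levels = ids))
  list(ids = ids, rows = rows_by_id)
}

boot_stat <- function(data, stat_fn, n_boot, seed, max_redraw = 10) {
  bi <- boot_indices(data$patient_id)
  n_id <- length(bi$ids)
  n_bad <- 0L
  withr::with_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(max_redraw)) {
        take <- sample.int(n_id, n_id, replace = TRUE)
        rows <- unlist(bi$rows[take], use.names = FALSE)
        val <- tryCatch(stat_fn(data[rows, , drop = FALSE]),
                        error = function(e) NULL)
        if (!is.null(val) && all(is.finite(unlist(val)))) break
        n_bad <- n_bad + 1L
        val <- NULL
      }
      if (is.null(val)) {
        stop("bootstrap statistic undefined on ", max_redraw,
             " consecutive resamples", call. = FALSE)
      }
      out[[b]] <- val
    }
    structure(out, n_redrawn = n_bad)
  })
}

#' Patient-level bootstrap confidence interval
#'
#' Percentile interval over `n_boot` resamples of patient visits (a resampled
#' visit brings all of its rows). Resamples on which the metric is undefined
#' are redrawn and counted (attribute `n_redrawn`).
#'
#' @param data Tibble with at least `patient_id`, `score`, `label`.
#' @param metric_fn Function of a resampled data tibble returning a scalar,
#'   e.g. `function(d) auroc(d$score, d$label)`.
#' @param n_boot Number of resamples (>= 100; default 1000).
#' @param seed Seed; the interval is deterministic given it.
#' @param level Coverage (default 0.95).
#' @return Named numeric `lo`, `hi` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(data, metric_fn, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  stopifnot(n_boot >= 100)
  vals <- boot_stat(data, metric_fn, n_boot, seed)
  v <- vapply(vals, identity, numeric(1))
  qs <- stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(c(lo = qs[1], hi = qs[2]), n_redrawn = attr(vals, "n_redrawn"))
}

#' Bootstrap t-test comparing two scorers' AUROC
#'
#' Paired patient-level resampling of the AUROC difference; the two-tailed
#' p-value comes from the t statistic of the bootstrap distribution
#' (`mean / sd` of the resampled differences, against a t reference with
#' `n_boot - 1` degrees of freedom). Identical scorers give a zero-variance
#' bootstrap distribution and p = 1 by convention.
#'
#' @param data Tibble with `patient_id`, `label` and two score columns.
#' @param score_a,score_b Names of the score columns being compared.
#' @param n_boot Resamples (default 1000).
#' @param seed Seed.
#' @return One-row tibble: `delta_auroc` (a minus b), `t`, `p_value`.
#' @export
bootstrap_auroc_test <- function(data, score_a, score_b, n_boot = 1000,
                                 seed = 1L) {
  stat <- function(d) auroc(d[[score_a]], d$label) - auroc(d[[score_b]],
                                                           d$label)
  point <- stat(data)
  vals <- vapply(boot_stat(data, stat, n_boot, seed), identity, numeric(1))
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    t_stat <- if (mean(vals) == 0) 0 else Inf * sign(mean(vals))
    p <- if (mean(vals) == 0) 1 else 0
  } else {
    t_stat <- mean(vals) / s
    p <- 2 * stats::pt(-abs(t_stat), df = n_boot - 1)
  }
  tibble::tibble(delta_auroc = point, t = t_stat, p_value = p)
}

#' Evaluate a scorer on visit-level data
#'
#' Computes AUROC, AUPRC and, at the requested threshold (default: the Youden
#' optimum), sensitivity, specificity, PPV, NPV and false alarms per 1,000
#' patients, each with a patient-level bootstrap percentile CI, plus the
#' risk-tier cutpoints.
#'
#' @param data Visit-level tibble: `patient_id`, `score`, `label` (one row per
#'   visit, e.g. from [aggregate_visits()]).
#' @param threshold Alarm threshold; `NULL` (default) uses [youden_cutoff()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param level CI coverage.
#' @param scorer Label stored in the report (e.g. `"tews"`, `"mews"`).
#' @param outcome Outcome label stored in the report.
#' @return A `tews_eval` object; `tidy()` gives the metric table, `glance()` a
#'   one-row summary.
#' @export
evaluate_scores <- function(data, threshold = NULL, n_boot = 1000, seed = 1L,
                            level = 0.95, scorer = "tews", outcome = NA) {
  stopifnot(all(c("patient_id", "score", "label") %in% names(data)))
  if (length(unique(data$label)) < 2) {
    stop("evaluation requires both classes", call. = FALSE)
  }
  thr <- threshold %||% youden_cutoff(data$score, data$label)
  tiers <- risk_tiers(data$score, data$label)
  metric_fns <- list(
    auroc = function(d) auroc(d$score, d$label),
    auprc = function(d) auprc(d$score, d$label),
    sensitivity = function(d) confusion_metrics(d$score, d$label,
                                                thr)$sensitivity,
    specificity = function(d) confusion_metrics(d$score, d$label,
                                                thr)$specificity,
    ppv = function(d) confusion_metrics(d$score, d$label, thr)$ppv,
    npv = function(d) confusion_metrics(d$score, d$label, thr)$npv,
    false_alarms_per_1000 = function(d)
      confusion_metrics(d$score, d$label, thr)$false_alarms_per_1000)
  # one bootstrap pass shared by all metrics for consistency and speed
  all_fn <- function(d) vapply(metric_fns, function(f) f(d), numeric(1))
  points <- all_fn(data)
  boots <- boot_stat(data, all_fn, n_boot, seed)
  bm <- do.call(rbind, boots)
  alpha <- (1 - level) / 2
  metrics <- tibble::tibble(
    metric = names(metric_fns),
    estimate = unname(points),
    conf.low = apply(bm, 2, stats::quantile, alpha, names = FALSE),
    conf.high = apply(bm, 2, stats::quantile, 1 - alpha, names = FALSE))
  structure(list(
    metrics = metrics, threshold = thr, tiers = tiers, scorer = scorer,
    outcome = outcome, n_visits = nrow(data), n_positive = sum(data$label),
    n_boot = n_boot, level = level,
    n_redrawn = attr(boots, "n_redrawn")), class = "tews_eval")
}

#' @export
print.tews_eval <- function(x, ...) {
  cat("<tews_eval> scorer '", x$scorer, "'",
      if (!is.na(x$outcome)) paste0(", outcome '", x$outcome, "'"), ": ",
      x$n_visits, " visits (", x$n_positive, " positive), threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_scores
#' @param x A `tews_eval`.
#' @param ... Unused.
#' @method tidy tews_eval
#' @export
tidy.tews_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, scorer = x$scorer, outcome = x$outcome,
                threshold = x$threshold, .before = 1)
}

#' @rdname evaluate_scores
#' @method glance tews_eval
#' @export
glance.tews_eval <- function(x, ...) {
  wide <- stats::setNames(as.list(x$metrics$estimate), x$metrics$metric)
  tibble::as_tibble(c(list(scorer = x$scorer, outcome = x$outcome,
                           threshold = x$threshold, n_visits = x$n_visits,
                           n_positive = x$n_positive), wide))
}
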
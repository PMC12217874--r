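# Evaluation metrics: closed-form examples, brute-force equivalence and
# bootstrap behaviour.

test_that("AUROC matches enumerated pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)  # all ties
  expect_error(auroc(1:3, c(1, 1, 1)), "single class")
  set.seed(41)
  for (trial in 1:40) {
    n <- sample(5:60, 1)
    scores <- sample(round(runif(n), 2))  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("AUPRC handles the canonical cases and matches the oracle", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(auprc(1:3, c(0, 0, 0)), "without positives")
  # 6-sample fixture, hand-walked: scores desc 0.9(1) 0.8(0) 0.7(1) 0.6(1)
  # 0.4(0) 0.2(0); recall steps at thresholds 0.9, 0.7, 0.6:
  # 1/3 * 1 + 1/3 * 2/3 + 1/3 * 3/4 = 0.8055...
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2), c(1, 0, 1, 1, 0, 0)),
               1 / 3 + 2 / 9 + 1 / 4, tolerance = 1e-12)
  set.seed(43)
  for (trial in 1:40) {
    n <- sample(5:60, 1)
    scores <- sample(round(runif(n), 2))
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
  }
})

test_that("Youden threshold maximises J with ties broken low", {
  # enumerated: at 0.7 sens 1, spec 0.5 (J .5); at 0.9 sens .5, spec 1 (J .5)
  expect_equal(youden_cutoff(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.7)
  expect_equal(youden_cutoff(rep(0.4, 4), c(1, 0, 1, 0)), 0.4)  # single value
  expect_error(youden_cutoff(1:3, rep(1, 3)), "single class")
  set.seed(47)
  for (trial in 1:40) {
    n <- sample(5:60, 1)
    scores <- sample(round(runif(n), 2))
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(youden_cutoff(scores, labels), oracle_youden(scores, labels))
  }
})

test_that("confusion metrics satisfy their algebraic identities", {
  set.seed(53)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.2)
  for (thr in quantile(scores, c(0.1, 0.5, 0.9))) {
    cm <- confusion_metrics(scores, labels, thr)
    n_neg <- sum(labels == 0)
    expect_equal(cm$false_alarms_per_1000,
                 1000 * (1 - cm$specificity) * n_neg / 200)
    expect_equal(cm$tp + cm$fn, sum(labels))
    expect_equal(cm$fp + cm$tn, n_neg)
  }
  low <- confusion_metrics(scores, labels, min(scores) - 1)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  fixed <- confusion_metrics(c(rep(1, 32), rep(0, 968)), rep(0, 1000), 0.5)
  expect_equal(fixed$false_alarms_per_1000, 32)
})

test_that("matched-sensitivity threshold is the closest achievable from above", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  labels <- c(1, 0, 1, 1, 0, 0)
  thr <- matched_sensitivity_threshold(scores, labels, 0.6)
  expect_equal(as.numeric(thr), 0.7)  # sens(0.7) = 2/3, sens(0.9) = 1/3
  expect_equal(attr(thr, "achieved_sensitivity"), 2 / 3)
  # reference 1 -> threshold at or below the lowest positive score
  thr1 <- matched_sensitivity_threshold(scores, labels, 1)
  expect_lte(as.numeric(thr1), 0.6)
  expect_error(matched_sensitivity_threshold(scores, labels, 0), "\\(0, 1\\]")
  set.seed(59)
  for (trial in 1:20) {
    scores <- runif(40)
    labels <- rbinom(40, 1, 0.3)
    if (sum(labels) == 0) next
    ref <- runif(1, 0.3, 1)
    thr <- matched_sensitivity_threshold(scores, labels, ref)
    sens <- mean(scores[labels == 1] >= as.numeric(thr))
    expect_gte(sens, ref)
    # one positive-count step higher threshold would undershoot the reference
    above <- sort(unique(scores))[sort(unique(scores)) > as.numeric(thr)]
    if (length(above) > 0) {
      expect_lt(mean(scores[labels == 1] >= min(above)), ref)
    }
  }
})

test_that("risk tiers partition the score range", {
  # overlapping scores: the 90%-sensitivity cut sits below the
  # 95%-specificity cut and all three tiers are populated
  set.seed(61)
  labels <- rbinom(600, 1, 0.25)
  scores <- plogis(2.5 * labels + rnorm(600))
  tiers <- risk_tiers(scores, labels)
  expect_lt(tiers$low_cut, tiers$high_cut)
  expect_gte(tiers$achieved_sensitivity, 0.90)
  expect_gte(tiers$achieved_specificity, 0.95)
  groups <- assign_risk_tiers(scores, tiers)
  expect_true(all(!is.na(groups)))
  expect_equal(levels(groups), c("low", "intermediate", "high"))
  expect_true(all(table(groups) > 0))
  expect_equal(length(groups), 600)
  # tiers are exhaustive and exclusive: each score lands in exactly one
  expect_equal(sum(table(groups)), 600)

  # perfectly separated toy: both anchors met inside the gap; every positive
  # lands in the high tier and no event-free patient does
  sep_scores <- c(runif(300, 0, 0.4), runif(40, 0.6, 1))
  sep_labels <- c(rep(0, 300), rep(1, 40))
  sep <- risk_tiers(sep_scores, sep_labels)
  expect_lte(sep$low_cut, sep$high_cut)
  sep_groups <- assign_risk_tiers(sep_scores, sep)
  # the 90%-sensitivity anchor leaves at most 10% of positives below low_cut
  expect_gte(mean(sep_groups[sep_labels == 1] == "high"), 0.90)
  expect_true(all(sep_groups[sep_labels == 0] != "high"))

  # degenerate constant scores collapse with a warning
  expect_warning(deg <- risk_tiers(c(rep(0.5, 9), 0.6),
                                   c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0)),
                 "collapse")
  expect_lte(deg$low_cut, deg$high_cut)
})

test_that("the patient-level bootstrap is deterministic and sane", {
  set.seed(67)
  d <- tibble::tibble(patient_id = sprintf("P%03d", 1:120),
                      score = runif(120), label = rbinom(120, 1, 0.3))
  f <- function(x) auroc(x$score, x$label)
  ci1 <- bootstrap_ci(d, f, n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(d, f, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  point <- f(d)
  expect_lte(ci1[["lo"]], point)
  expect_gte(ci1[["hi"]], point)
  # constant metric: zero-width interval
  cic <- bootstrap_ci(d, function(x) 0.42, n_boot = 100, seed = 2)
  expect_equal(as.numeric(cic), c(0.42, 0.42))
  # width shrinks with sample size
  big <- tibble::tibble(patient_id = sprintf("P%04d", 1:1200),
                        score = runif(1200), label = rbinom(1200, 1, 0.3))
  ci_big <- bootstrap_ci(big, f, n_boot = 200, seed = 9)
  expect_lt(diff(unname(ci_big)), diff(unname(ci1)))
})

test_that("percentile intervals cover the point estimate across repetitions", {
  set.seed(71)
  hits <- 0
  for (rep in 1:20) {
    d <- tibble::tibble(patient_id = sprintf("P%03d", 1:80),
                        score = runif(80), label = rbinom(80, 1, 0.4))
    f <- function(x) auroc(x$score, x$label)
    ci <- bootstrap_ci(d, f, n_boot = 150, seed = rep)
    p <- f(d)
    if (ci[["lo"]] <= p && p <= ci[["hi"]]) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the bootstrap AUROC test separates scorers as expected", {
  set.seed(73)
  n <- 400
  labels <- rbinom(n, 1, 0.25)
  strong <- labels + rnorm(n, 0, 0.4)
  noise <- runif(n)
  d <- tibble::tibble(patient_id = sprintf("P%04d", 1:n), label = labels,
                      strong = strong, noise = noise)
  same <- bootstrap_auroc_test(dplyr::mutate(d, a = strong, b = strong),
                               "a", "b", n_boot = 200, seed = 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$delta_auroc, 0)
  diff_test <- bootstrap_auroc_test(d, "strong", "noise", n_boot = 300,
                                    seed = 2)
  expect_lt(diff_test$p_value, 0.05)
  expect_gt(diff_test$delta_auroc, 0)
  expect_gte(diff_test$p_value, 0)
  expect_lte(diff_test$p_value, 1)
})

test_that("evaluate_scores assembles a coherent report", {
  set.seed(79)
  n <- 250
  labels <- rbinom(n, 1, 0.2)
  d <- tibble::tibble(patient_id = sprintf("P%04d", 1:n),
                      score = plogis(2 * labels + rnorm(n)), label = labels)
  ev <- evaluate_scores(d, n_boot = 150, seed = 5, scorer = "toy",
                        outcome = "vasopressor")
  td <- tidy(ev)
  expect_setequal(td$metric, c("auroc", "auprc", "sensitivity",
                               "specificity", "ppv", "npv",
                               "false_alarms_per_1000"))
  expect_true(all(td$conf.low <= td$estimate + 1e-12))
  expect_true(all(td$estimate <= td$conf.high + 1e-12))
  rates <- td[td$metric != "false_alarms_per_1000", ]
  expect_true(all(rates$estimate >= 0 & rates$estimate <= 1))
  fa <- td$estimate[td$metric == "false_alarms_per_1000"]
  expect_true(fa >= 0 && fa <= 1000)
  expect_equal(ev$threshold, youden_cutoff(d$score, d$label))
  gl <- glance(ev)
  expect_equal(gl$n_visits, n)
  expect_error(evaluate_scores(dplyr::mutate(d, label = 0)), "both classes")
  # aggregation helper: max score and any-label semantics
  win <- tibble::tibble(patient_id = c("a", "a", "b"),
                        .pred = c(0.2, 0.7, 0.1), label = c(0, 1, 0))
  vis <- aggregate_visits(win)
  expect_equal(vis$score, c(0.7, 0.1))
  expect_equal(vis$label, c(1, 0))
})
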
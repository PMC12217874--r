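# Preprocessing: outlier filtering, scaling, binning, windowing, labelling
# and static encoding, anchored by brute-force oracles.

test_that("outlier filtering drops out-of-range values, keeps boundaries", {
  vars <- default_variables()
  ev <- tibble::tibble(
    variable = c("sbp", "sbp", "sbp", "hr", "hr", "temp"),
    value = c(400, 30, 300, 9.9, 10, 36.5))
  out <- filter_outliers(ev, vars)
  expect_equal(out$value, c(30, 300, 10, 36.5))  # closed interval retained
  removed <- attr(out, "n_removed")
  expect_equal(removed$n_removed[removed$variable == "sbp"], 1L)
  expect_equal(removed$n_removed[removed$variable == "hr"], 1L)
  expect_equal(sum(removed$n_removed), 2L)
  # identity when everything is in range
  ok <- tibble::tibble(variable = "hr", value = c(60, 80))
  expect_equal(filter_outliers(ok, vars)$value, c(60, 80))
  expect_error(filter_outliers(tibble::tibble(variable = "xyz", value = 1),
                               vars), "unknown variable")
})

test_that("min-max scaling maps the range onto [0, 1]", {
  expect_equal(scale_minmax(30, 30, 300), 0)
  expect_equal(scale_minmax(300, 30, 300), 1)
  expect_equal(scale_minmax(165, 30, 300), 0.5)
  expect_warning(out <- scale_minmax(c(-5, 400), 30, 300), "clipped")
  expect_equal(out, c(0, 1))
})

test_that("binning keeps the last value per 15-min bin, half-open at the end", {
  feats <- feature_set("full")
  end <- utc("2024-03-03 12:00:00")
  ev <- tibble::tibble(
    patient_id = "A",
    timestamp = c(end - 10 * 60, end - 7 * 60,   # same final bin, 3 min apart
                  end,                           # exactly at end: excluded
                  end - 48 * 3600,               # exactly window start: bin 1
                  end - 48 * 3600 - 1),          # before window: excluded
    variable = "hr",
    value = c(0.1, 0.2, 0.9, 0.5, 0.7))
  r <- resample_to_bins(ev, end, feats)
  hr <- which(feats$variable == "hr")
  expect_equal(unname(r$X[192, hr]), 0.2)   # later of the two in-bin values wins
  expect_equal(unname(r$X[1, hr]), 0.5)     # inclusive window start
  expect_equal(sum(r$mask[, hr]), 2)
  expect_equal(sum(r$mask[, -hr]), 0)
  # empty input
  r0 <- resample_to_bins(ev[0, ], end, feats)
  expect_equal(sum(r0$X), 0)
  expect_equal(dim(r0$X), c(192L, 13L))
  # one value per bin for 48 h fills the whole column
  full <- tibble::tibble(
    patient_id = "A",
    timestamp = end - 60 * 15 * (192:1) + 60,
    variable = "hr", value = 0.5)
  rf <- resample_to_bins(full, end, feats)
  expect_equal(sum(rf$mask[, hr]), 192)
})

test_that("in-bin ties at identical timestamps resolve to the later row", {
  feats <- feature_set("full")
  end <- utc("2024-03-03 12:00:00")
  ev <- tibble::tibble(patient_id = "A",
                       timestamp = rep(end - 5 * 60, 2),
                       variable = "hr", value = c(0.3, 0.8))
  r <- resample_to_bins(ev, end, feats)
  expect_equal(unname(r$X[192, which(feats$variable == "hr")]), 0.8)
})

test_that("a 1-hour stay at 15-min cadence yields 5 prediction points", {
  cohort <- simple_patient(los_hours = 1, gap_minutes = 15)
  w <- build_windows(cohort, feature_set("full"), cadence_minutes = 15)
  expect_equal(nrow(w$index), 5)
  expect_equal(as.numeric(difftime(w$index$prediction_time,
                                   min(cohort$events$timestamp),
                                   units = "mins")),
               c(0, 15, 30, 45, 60))
})

test_that("every window materialises with exactly 192 rows", {
  cohort <- simple_patient(los_hours = 3)
  w <- build_windows(cohort, feature_set("full"), cadence_minutes = 60)
  dense <- window_tensor(w)
  expect_equal(dim(dense$X)[1:2], c(192L, 13L))
  expect_equal(dim(dense$mask), dim(dense$X))
})

test_that("labels follow the half-open 24-h horizon", {
  arr <- utc("2024-03-01 08:00:00")
  oc <- tibble::tibble(patient_id = "A",
                       event_type = c("vasopressor", "septic_shock"),
                       timestamp = c(arr + 23 * 3600, arr + 25 * 3600))
  labs <- assign_labels(oc, arr)
  expect_equal(labs[["vasopressor"]], 1L)   # +23 h -> 1
  expect_equal(labs[["septic_shock"]], 0L)  # +25 h -> 0
  expect_equal(sum(assign_labels(oc[0, ], arr)), 0L)
  # boundary: exactly +24 h is inside, exactly at the prediction time is not
  oc2 <- tibble::tibble(patient_id = "A", event_type = "vasopressor",
                        timestamp = arr + 24 * 3600)
  expect_equal(assign_labels(oc2, arr)[["vasopressor"]], 1L)
  expect_equal(assign_labels(oc2, arr + 24 * 3600)[["vasopressor"]], 0L)
})

test_that("windows at or after a patient's own event are ineligible", {
  arr <- utc("2024-03-01 08:00:00")
  oc <- tibble::tibble(patient_id = "A", event_type = "vasopressor",
                       timestamp = arr + 3600)
  cohort <- simple_patient(los_hours = 3, gap_minutes = 30, arrival = arr,
                           outcomes = oc)
  w <- build_windows(cohort, feature_set("full"), cadence_minutes = 30)
  idx <- w$index
  expect_true(all(idx$elig_vasopressor == (idx$prediction_time <
                                             arr + 3600)))
  expect_true(all(idx$elig_septic_shock))  # other outcomes unaffected
  # labels are monotone within the eligible range
  el <- idx[idx$elig_vasopressor, ]
  expect_true(all(diff(el$label_vasopressor[order(el$prediction_time)]) >= 0))
})

test_that("an adverse event before arrival is a data-integrity error", {
  arr <- utc("2024-03-01 08:00:00")
  oc <- tibble::tibble(patient_id = "A", event_type = "vasopressor",
                       timestamp = arr - 60)
  cohort <- simple_patient(arrival = arr, outcomes = oc)
  expect_error(build_windows(cohort), "before arrival.*A")
})

test_that("static encoding follows the documented coding", {
  st <- tibble::tibble(patient_id = c("A", "B", "C"),
                       age = c(19, 64.5, 110),
                       sex = c("female", "male", "female"),
                       arrival = c("ambulance", "other", "other"),
                       t_arrival = utc("2024-01-01"),
                       t_departure = utc("2024-01-02"))
  enc <- encode_static(st)
  expect_equal(enc$age, c(0, 0.5, 1))
  expect_equal(enc$sex, c(1, 0, 1))
  expect_equal(enc$arrival, c(1, 0, 0))
  expect_equal(ncol(encode_static(st, include_arrival = FALSE)) - 1L, 2L)
  st$age[2] <- NA
  expect_error(encode_static(st), "missing static.*B")
  st$age[2] <- 17
  expect_error(encode_static(st), "age below 19.*B")
})

test_that("windowing and labelling agree with brute-force oracles", {
  feats <- feature_set("full")
  set.seed(99)
  for (trial in 1:30) {
    arr <- utc("2024-04-01 00:00:00") + round(runif(1, 0, 1e6))
    los <- runif(1, 0.5, 60)
    ev <- random_events(sample(5:50, 1), arr, los)
    end <- arr + round(runif(1, 0, los * 3600))
    got <- resample_to_bins(ev, end, feats)
    want <- oracle_bins(ev, end, feats)
    expect_equal(unname(got$X), want$X)
    expect_equal(unname(got$mask), want$mask)

    oc <- tibble::tibble(
      patient_id = "R",
      event_type = sample(tewsr:::AE_TYPES, 3, replace = TRUE),
      timestamp = arr + round(runif(3, 0, los * 3600)))
    expect_equal(assign_labels(oc, end), oracle_labels(oc, end))
  }
})

test_that("build_windows matches per-window resampling and conserves entries", {
  set.seed(123)
  arr <- utc("2024-05-01 10:00:00")
  los <- 10
  feats <- feature_set("full")
  ev <- random_events(80, arr, los)
  ev$value <- round(ev$value * 100 + 50, 2)  # raw-ish values inside ranges
  ev <- ev[ev$value >= 0, ]
  # place values inside each variable's range so nothing is filtered
  fi <- match(ev$variable, feats$variable)
  ev$value <- feats$lo[fi] + (feats$hi[fi] - feats$lo[fi]) *
    round(runif(nrow(ev)), 3)
  st <- tibble::tibble(patient_id = "R", age = 40, sex = "male",
                       arrival = "other", t_arrival = arr,
                       t_departure = arr + los * 3600)
  cohort <- make_cohort(ev, st)
  w <- build_windows(cohort, feats, cadence_minutes = 45)
  dense <- window_tensor(w)
  scaled <- ev
  scaled$value <- (ev$value - feats$lo[fi]) / (feats$hi[fi] - feats$lo[fi])
  for (i in seq_len(nrow(w$index))) {
    want <- oracle_bins(scaled, w$index$prediction_time[i], feats)
    expect_equal(unname(dense$X[, , i]), want$X)
    # conservation: sparse rows for this window = observed mask entries
    expect_equal(sum(w$values$window_id == w$index$window_id[i]),
                 sum(want$mask))
  }
})

test_that("preprocessing is bit-reproducible", {
  cohort <- generate_cohort(cohort_spec(50, prevalence = 0.2, seed = 55))
  a <- build_windows(cohort, feature_set("full"), cadence_minutes = 30)
  b <- build_windows(cohort, feature_set("full"), cadence_minutes = 30)
  expect_identical(a$values, b$values)
  expect_identical(a$index, b$index)
})
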
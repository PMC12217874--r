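# Transformer risk model: encoding, loss, gradients, training behaviour,
# determinism and architectural contracts.

tiny_cfg <- function(...) {
  model_config(n_features = 3, static_dim = 2, d_model = 4L, n_layers = 2L,
               t_steps = 6L, d_ff = 8L, d_static = 3L, dropout = 0,
               batch_size = 4L, epochs = 1L, seed = 7L, ...)
}

tiny_inputs <- function(b = 4L, t = 6L, n = 3L, k = 2L, seed = 2) {
  withr::with_seed(seed, list(
    X = array(runif(t * n * b), c(t, n, b)),
    S = matrix(runif(b * k), b, k),
    y = rep(c(1, 0), length.out = b),
    fb = rep(1L, b)))
}

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(4, 6)
  expect_equal(pe[1, ], c(0, 1, 0, 1, 0, 1))          # pos = 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)   # pos = 1, i = 0
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 6)), tolerance = 1e-12)
  big <- positional_encoding(192, 512)
  expect_true(all(big >= -1 & big <= 1))
  expect_equal(dim(big), c(192L, 512L))
})

test_that("model configuration enforces its contracts", {
  expect_error(model_config(13, 3, n_heads = 2L), "single-head")
  expect_error(model_config(13, 3, dropout = 1), "dropout")
  cfg <- model_config(13, 3)
  expect_equal(cfg$loss_weights, c(pos = 5.495, neg = 0.505))
})

test_that("weighted BCE matches hand arithmetic and reduces to plain BCE", {
  expect_equal(weighted_bce(1, 0.5), 5.495 * log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(1, 0.5, 1, 1), log(2), tolerance = 1e-12)
  # weights (1,1) equal the mean of per-sample BCE to 1e-10
  set.seed(3)
  y <- rbinom(50, 1, 0.4)
  p <- runif(50, 0.01, 0.99)
  per_sample <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(y, p, 1, 1), mean(per_sample), tolerance = 1e-10)
  # probabilities at exactly 0/1 are clamped, not infinite
  expect_true(is.finite(weighted_bce(c(1, 0), c(0, 1))))
  # loss of a confident correct prediction approaches 0
  expect_lt(weighted_bce(1, 1 - 1e-9), 1e-5)
})

test_that("balanced class weights follow N / (2 N_c)", {
  expect_equal(compute_class_weights(c(rep(1, 10), rep(0, 90))),
               c(pos = 5, neg = 100 / 180))
  expect_equal(compute_class_weights(rep(c(0, 1), 25)), c(pos = 1, neg = 1))
  w <- compute_class_weights(c(rep(1, 91), rep(0, 909)))
  expect_equal(unname(w["pos"]), 5.4945, tolerance = 1e-4)  # ~printed pair
  expect_error(compute_class_weights(rep(0, 10)), "both classes")
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  p <- tewsr:::init_params(cfg)
  pe <- positional_encoding(cfg$t_steps, cfg$d_model)
  inp <- tiny_inputs()
  for (pooling in 0:1) {
    fb <- if (pooling == 1) c(2L, 1L, 3L, 7L) else inp$fb
    loss_of <- function(pp) {
      tewsr:::cpp_tews_train_batch(pp, pe, inp$X, inp$S, inp$y, 2.5, 0.7,
                                   cfg$n_layers, pooling, fb, 0, 1,
                                   1e-7)$loss
    }
    res <- tewsr:::cpp_tews_train_batch(p, pe, inp$X, inp$S, inp$y, 2.5,
                                        0.7, cfg$n_layers, pooling, fb, 0,
                                        1, 1e-7)
    h <- 1e-6
    set.seed(11)
    for (nm in names(p)) {
      for (i in sample(seq_along(p[[nm]]), min(3, length(p[[nm]])))) {
        pp <- p
        pp[[nm]][i] <- pp[[nm]][i] + h
        up <- loss_of(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * h
        dn <- loss_of(pp)
        fd <- (up - dn) / (2 * h)
        an <- as.numeric(res$grads[[nm]])[i]
        expect_lt(abs(fd - an) / max(1e-8, abs(fd), abs(an)), 1e-4)
      }
    }
  }
})

test_that("the forward pass is a valid probability and zero head gives 0.5", {
  cfg <- tiny_cfg()
  p <- tewsr:::init_params(cfg)
  pe <- positional_encoding(cfg$t_steps, cfg$d_model)
  inp <- tiny_inputs(b = 8L)
  pr <- tewsr:::cpp_tews_predict(p, pe, inp$X, inp$S, cfg$n_layers, 0L,
                                 rep(1L, 8))
  expect_true(all(pr > 0 & pr < 1))
  p0 <- p
  p0$head_w[] <- 0
  p0$head_b <- 0
  pr0 <- tewsr:::cpp_tews_predict(p0, pe, inp$X, inp$S, cfg$n_layers, 0L,
                                  rep(1L, 8))
  expect_equal(as.numeric(pr0), rep(0.5, 8))
})

test_that("column permutation with matched metadata leaves predictions fixed,
           time-row permutation does not", {
  cfg <- tiny_cfg()
  p <- tewsr:::init_params(cfg)
  pe <- positional_encoding(cfg$t_steps, cfg$d_model)
  inp <- tiny_inputs(b = 3L)
  base <- tewsr:::cpp_tews_predict(p, pe, inp$X, inp$S, cfg$n_layers, 0L,
                                   rep(1L, 3))
  perm <- c(3, 1, 2)
  Xp <- inp$X[, perm, , drop = FALSE]
  pp <- p
  pp$Win <- p$Win[perm, , drop = FALSE]  # reorder input projection rows too
  got <- tewsr:::cpp_tews_predict(pp, pe, Xp, inp$S, cfg$n_layers, 0L,
                                  rep(1L, 3))
  expect_equal(as.numeric(got), as.numeric(base), tolerance = 1e-12)
  # shuffling TIME rows (PE unchanged) must change the output
  rperm <- c(6, 1, 5, 2, 4, 3)
  Xr <- inp$X[rperm, , , drop = FALSE]
  got_r <- tewsr:::cpp_tews_predict(p, pe, Xr, inp$S, cfg$n_layers, 0L,
                                    rep(1L, 3))
  expect_false(isTRUE(all.equal(as.numeric(got_r), as.numeric(base),
                                tolerance = 1e-6)))
})

test_that("training refuses single-class data and mismatched shapes", {
  fit <- tiny_trained_model()
  zero <- generate_cohort(cohort_spec(30, prevalence = 0, seed = 61))
  wz <- build_windows(zero, feature_set("vitals_only"), cadence_minutes = 60)
  sz <- split_cohort(zero, seed = 62)
  expect_error(train_tews(wz, "vasopressor", fit$config, sz),
               "both classes")
  bad_cfg <- model_config(n_features = 13, static_dim = 3, d_model = 16L,
                          n_layers = 2L, t_steps = 192L)
  expect_error(train_tews(fit$windows, "icu_admission", bad_cfg, fit$split),
               "expected \\(192, 6\\)")
})

test_that("training reduces the loss on drift-separated synthetic data and is
           deterministic under the seed", {
  fit <- tiny_trained_model()
  h <- fit$model$history
  expect_equal(nrow(h), 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  # identical rerun
  ids <- select_train_windows(
    fit$windows, "icu_admission",
    fit$split$patient_id[fit$split$partition == "train"], 2L, 404L)
  refit <- train_tews(fit$windows, "icu_admission", fit$config, fit$split,
                      train_window_ids = ids)
  expect_equal(refit$history, fit$model$history)
  expect_equal(refit$params, fit$model$params)
  p1 <- predict(fit$model, fit$windows)
  p2 <- predict(refit, fit$windows)
  expect_equal(p1$.pred, p2$.pred)
})

test_that("the published full-size configuration builds and runs forward", {
  cfg <- model_config(n_features = 13, static_dim = 3)  # 4 x 512, T = 192
  expect_equal(cfg$n_layers, 4L)
  expect_equal(cfg$d_model, 512L)
  p <- tewsr:::init_params(cfg)
  pe <- positional_encoding(192, 512)
  set.seed(5)
  X <- array(runif(192 * 13 * 2), c(192, 13, 2))
  S <- matrix(runif(6), 2, 3)
  pr <- tewsr:::cpp_tews_predict(p, pe, X, S, 4L, 0L, rep(1L, 2))
  expect_true(all(pr > 0 & pr < 1))
})

test_that("fine-tuning guards its preconditions and fraction 0 is identity", {
  fit <- tiny_trained_model()
  expect_identical(fine_tune(fit$model, fit$windows, 0), fit$model)
  expect_error(fine_tune(fit$model, fit$windows, -0.1), "fraction")
  all_ids <- unique(fit$windows$index$patient_id)
  expect_error(fine_tune(fit$model, fit$windows, 0.05, eval_ids = all_ids),
               "outside the evaluation split")
  tuned <- fine_tune(fit$model, fit$windows, 0.05, seed = 88, epochs = 1L)
  expect_s3_class(tuned, "tews_model")
  expect_false(identical(tuned$params, fit$model$params))
  expect_equal(tuned$provenance$fine_tune$fraction, 0.05)
})

test_that("tidy and glance summarise a fitted model", {
  fit <- tiny_trained_model()
  td <- tidy(fit$model)
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  gl <- glance(fit$model)
  expect_equal(gl$outcome, "icu_admission")
  expect_equal(gl$epochs, 6L)
  expect_gt(gl$n_parameters, 0)
})

test_that("model checkpoints round-trip with a verified manifest", {
  fit <- tiny_trained_model()
  dir <- withr::local_tempdir()
  save_tews_model(fit$model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_tews_model(dir)
  p1 <- predict(fit$model, fit$windows,
                window_ids = fit$windows$index$window_id[1:20])
  p2 <- predict(back, fit$windows,
                window_ids = fit$windows$index$window_id[1:20])
  expect_equal(p1$.pred, p2$.pred)
  # a tampered checkpoint is rejected
  tampered <- readRDS(file.path(dir, "model.rds"))
  tampered$params$head_b <- tampered$params$head_b + 1
  saveRDS(tampered, file.path(dir, "model.rds"))
  expect_error(load_tews_model(dir), "does not match")
})
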
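# Transformer risk model: configuration, initialisation, weighted loss,
# AdamW training with best-validation-checkpoint selection, prediction and
# transfer-learning fine-tuning. One independent model is fitted per outcome.

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d))` and `(pos, 2i+1)` is the
#' matching cosine, with `pos` counted from 0; all values lie in `[-1, 1]`.
#'
#' @param t_steps Number of time steps (rows).
#' @param d_model Embedding dimension (columns).
#' @return A `t_steps x d_model` matrix.
#' @export
#' @examples
#' positional_encoding(4, 6)[1, ]  # row pos = 0: sin terms 0, cos terms 1
positional_encoding <- function(t_steps, d_model) {
  stopifnot(t_steps >= 1, d_model >= 1)
  pos <- seq_len(t_steps) - 1
  i2 <- 2 * (seq_len(ceiling(d_model / 2)) - 1)       # 0, 2, 4, ...
  ang <- outer(pos, 10000^(i2 / d_model), "/")
  pe <- matrix(0, t_steps, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)
  if (d_model > 1) {
    n_cos <- floor(d_model / 2)
    pe[, seq(2, d_model, by = 2)] <- cos(ang[, seq_len(n_cos), drop = FALSE])
  }
  pe
}

#' Model configuration
#'
#' Architecture and optimisation settings. The defaults are the published
#' configuration: a 4-layer transformer encoder with single-head
#' self-attention and hidden dimension 512 over 192 time steps, AdamW with
#' learning rate 1e-4, batch size 1000, 200 epochs, and class weights
#' (5.495, 0.505). Set `loss_weights = "auto"` to compute balanced weights
#' from the training labels instead (see [compute_class_weights()]).
#'
#' @param n_features Number of time-series variables N.
#' @param static_dim Length k of the encoded static vector.
#' @param d_model Encoder hidden dimension.
#' @param n_layers Number of encoder layers.
#' @param n_heads Attention heads; this implementation is single-head, so the
#'   value must be 1 (as published).
#' @param t_steps Time steps per window.
#' @param d_ff Feed-forward inner dimension (default `2 * d_model`).
#' @param d_static Hidden width of the fully connected layer on statics.
#' @param dropout Dropout rate on the two residual branches.
#' @param learning_rate,weight_decay,batch_size,epochs AdamW settings.
#' @param loss_weights Numeric `(pos, neg)` pair or `"auto"`.
#' @param pooling `"last"` (final-time-step encoder state, default) or
#'   `"mean"` (mean over time steps from the first observed bin).
#' @param seed Integer seed controlling initialisation, batch order and
#'   dropout.
#' @return A `tews_config` list.
#' @export
model_config <- function(n_features, static_dim, d_model = 512L,
                         n_layers = 4L, n_heads = 1L, t_steps = 192L,
                         d_ff = 2L * d_model, d_static = 16L, dropout = 0.1,
                         learning_rate = 1e-4, weight_decay = 1e-2,
                         batch_size = 1000L, epochs = 200L,
                         loss_weights = c(pos = 5.495, neg = 0.505),
                         pooling = c("last", "mean"), seed = 1L) {
  if (n_heads != 1L) {
    stop("only single-head self-attention is implemented (n_heads = 1)",
         call. = FALSE)
  }
  if (d_model %% n_heads != 0) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  stopifnot(n_features >= 1, static_dim >= 1, d_model >= 2, n_layers >= 1,
            t_steps >= 1, d_ff >= 1, d_static >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1,
            epochs >= 1)
  if (!identical(loss_weights, "auto")) {
    stopifnot(is.numeric(loss_weights), length(loss_weights) == 2,
              all(loss_weights > 0))
    loss_weights <- stats::setNames(as.numeric(loss_weights), c("pos", "neg"))
  }
  structure(list(
    n_features = as.integer(n_features), static_dim = as.integer(static_dim),
    d_model = as.integer(d_model), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), t_steps = as.integer(t_steps),
    d_ff = as.integer(d_ff), d_static = as.integer(d_static),
    dropout = dropout, learning_rate = learning_rate,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), loss_weights = loss_weights,
    pooling = match.arg(pooling), seed = as.integer(seed)
  ), class = "tews_config")
}

# Xavier-uniform initialisation of all parameter tensors, deterministic in
# the configuration seed.
init_params <- function(config) {
  xavier <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  d <- config$d_model
  withr::with_seed(config$seed, {
    p <- list(Win = xavier(config$n_features, d), bin = numeric(d))
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      p[[paste0(pre, "Wq")]] <- xavier(d, d)
      p[[paste0(pre, "Wk")]] <- xavier(d, d)
      p[[paste0(pre, "Wv")]] <- xavier(d, d)
      p[[paste0(pre, "Wo")]] <- xavier(d, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- xavier(d, config$d_ff)
      p[[paste0(pre, "b1")]] <- numeric(config$d_ff)
      p[[paste0(pre, "W2")]] <- xavier(config$d_ff, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p$lnf_g <- rep(1, d)
    p$lnf_b <- numeric(d)
    p$Ws <- xavier(config$static_dim, config$d_static)
    p$bs <- numeric(config$d_static)
    p$head_w <- as.numeric(xavier(d + config$d_static, 1))
    p$head_b <- 0
    p
  })
}

#' Class-weighted binary cross-entropy
#'
#' `-(1/N) sum( w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p) )`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`. With weights (1, 1) this is
#' the ordinary mean binary cross-entropy.
#'
#' @param y 0/1 labels.
#' @param yhat Predicted probabilities in (0, 1).
#' @param w_pos,w_neg Class weights (defaults are the published pair).
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' weighted_bce(1, 0.5)  # 5.495 * log(2)
weighted_bce <- function(y, yhat, w_pos = 5.495, w_neg = 0.505) {
  stopifnot(length(y) == length(yhat), all(y %in% c(0, 1)))
  eps <- tews_constants()$prob_eps
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))
}

#' Balanced class weights
#'
#' The balanced rule `w_c = N / (2 * N_c)`, equal to scikit-learn's
#' `compute_class_weight("balanced")` for two classes. Note the published
#' default pair (5.495, 0.505) is mutually inconsistent under this rule
#' (5.495 implies about 9.1% positives, 0.505 about 1.0%); it is kept
#' verbatim as the default configuration value, and this function provides
#' the reproducible alternative.
#'
#' @param labels 0/1 vector containing both classes.
#' @return Named numeric: `pos`, `neg`.
#' @export
#' @examples
#' compute_class_weights(c(rep(1, 10), rep(0, 90)))  # (5.0, 0.556)
compute_class_weights <- function(labels) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == n) {
    stop("both classes must be present to compute class weights",
         call. = FALSE)
  }
  c(pos = n / (2 * n_pos), neg = n / (2 * (n - n_pos)))
}

# One AdamW step over the named parameter list. Layer-norm parameters and
# biases are excluded from weight decay, as is standard.
adamw_step <- function(state, grads, lr, wd, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decay_ok <- grepl("^(Win|l[0-9]+_(Wq|Wk|Wv|Wo|W1|W2)|Ws|head_w)$",
                    names(state$params))
  for (i in seq_along(state$params)) {
    g <- grads[[names(state$params)[i]]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^step)
    vhat <- state$v[[i]] / (1 - beta2^step)
    upd <- mhat / (sqrt(vhat) + eps)
    if (decay_ok[i]) upd <- upd + wd * state$params[[i]]
    state$params[[i]] <- state$params[[i]] - lr * upd
  }
  state
}

# Assemble the modelling frame for one outcome: eligible windows only.
outcome_frame <- function(windows, outcome) {
  stopifnot(outcome %in% AE_TYPES)
  idx <- windows$index
  keep <- idx[[paste0("elig_", outcome)]]
  tibble::tibble(window_id = idx$window_id[keep],
                 patient_id = idx$patient_id[keep],
                 prediction_time = idx$prediction_time[keep],
                 label = idx[[paste0("label_", outcome)]][keep])
}

#' Train a transformer risk model for one outcome
#'
#' Minimises the class-weighted binary cross-entropy with AdamW over
#' mini-batches; after each epoch the validation loss is computed (dropout
#' off) and the parameters with the lowest validation loss are retained.
#' Fully deterministic given `config$seed`.
#'
#' @param windows A [build_windows()] result.
#' @param outcome One of the five event types (see `tewsr:::AE_TYPES`).
#' @param config A [model_config()]; `n_features`, `static_dim` and `t_steps`
#'   must match the windows.
#' @param split Patient partition from [split_cohort()]; training uses the
#'   `train` partition, checkpoint selection the `validation` partition.
#' @param train_window_ids Optional subset of window ids to train on (e.g. a
#'   per-patient subsample); defaults to all eligible train-partition windows.
#' @param val_window_ids Optional subset of window ids for the per-epoch
#'   validation loss; defaults to all eligible validation-partition windows.
#' @return A `tews_model`: best parameters, configuration, resolved class
#'   weights, per-epoch loss history and provenance.
#' @export
train_tews <- function(windows, outcome, config, split,
                       train_window_ids = NULL, val_window_ids = NULL) {
  stopifnot(inherits(windows, "tews_windows"), inherits(config, "tews_config"))
  if (config$n_features != nrow(windows$features) ||
      config$t_steps != windows$t_steps) {
    stop("config does not match windows: expected (", windows$t_steps, ", ",
         nrow(windows$features), "), got config (", config$t_steps, ", ",
         config$n_features, ")", call. = FALSE)
  }
  frame <- outcome_frame(windows, outcome)
  part <- split$partition[match(frame$patient_id, split$patient_id)]
  tr <- frame[!is.na(part) & part == "train", ]
  va <- frame[!is.na(part) & part == "validation", ]
  if (!is.null(train_window_ids)) {
    tr <- tr[tr$window_id %in% train_window_ids, ]
  }
  if (!is.null(val_window_ids)) {
    va <- va[va$window_id %in% val_window_ids, ]
  }
  if (nrow(tr) == 0 || length(unique(tr$label)) < 2) {
    stop("training data must contain both classes for outcome '", outcome,
         "'", call. = FALSE)
  }
  cw <- if (identical(config$loss_weights, "auto")) {
    compute_class_weights(tr$label)
  } else config$loss_weights
  k_have <- ncol(windows$statics) - 1L
  if (config$static_dim != k_have) {
    stop("config does not match windows: static_dim ", config$static_dim,
         " vs encoded statics ", k_have, call. = FALSE)
  }

  cache <- make_tensor_cache(windows)
  pe <- positional_encoding(config$t_steps, config$d_model)
  pooling <- if (config$pooling == "last") 0L else 1L
  state <- list(params = init_params(config))
  state$m <- lapply(state$params, function(x) x * 0)
  state$v <- state$m

  # validation tensors are materialised once, in chunks, and reused per epoch
  val_chunks <- NULL
  if (nrow(va) > 0) {
    starts <- seq(1, nrow(va), by = 1024)
    val_chunks <- lapply(starts, function(bs) {
      sel <- bs:min(bs + 1023, nrow(va))
      list(batch = tensor_batch(cache, match(va$window_id[sel],
                                             cache$window_ids)),
           labels = va$label[sel])
    })
  }
  eval_loss <- function(params) {
    tot <- 0
    for (ch in val_chunks) {
      pr <- cpp_tews_predict(params, pe, ch$batch$X, ch$batch$S,
                             config$n_layers, pooling, ch$batch$first_bin)
      tot <- tot + weighted_bce(ch$labels, as.numeric(pr), cw[["pos"]],
                                cw[["neg"]]) * length(ch$labels)
    }
    tot / nrow(va)
  }

  n_tr <- nrow(tr)
  history <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                            val_loss = numeric(0))
  best <- list(loss = Inf, params = state$params, epoch = 0L)
  step <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      batch_starts <- seq(1, n_tr, by = config$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        ids <- ord[bs:min(bs + config$batch_size - 1, n_tr)]
        batch <- tensor_batch(cache, match(tr$window_id[ids],
                                           cache$window_ids))
        step <- step + 1L
        res <- cpp_tews_train_batch(
          state$params, pe, batch$X, batch$S, tr$label[ids],
          cw[["pos"]], cw[["neg"]], config$n_layers, pooling,
          batch$first_bin, config$dropout,
          config$seed * 1e5 + step, tews_constants()$prob_eps)
        if (!is.finite(res$loss)) {
          stop("non-finite training loss (epoch ", epoch, ", step ", step,
               ", lr ", config$learning_rate, ", batch ", config$batch_size,
               ")", call. = FALSE)
        }
        ep_loss <- ep_loss + res$loss * length(ids)
        state <- adamw_step(state, res$grads, config$learning_rate,
                            config$weight_decay, step)
      }
      vl <- if (is.null(val_chunks)) NA_real_ else eval_loss(state$params)
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = epoch, train_loss = ep_loss / n_tr, val_loss = vl))
      if (!is.na(vl) && vl < best$loss) {
        best <- list(loss = vl, params = state$params, epoch = epoch)
      }
    }
  })
  if (is.null(val_chunks)) {
    best <- list(loss = NA_real_, params = state$params,
                 epoch = config$epochs)
  }

  structure(list(
    outcome = outcome, config = config, params = best$params,
    class_weights = cw, history = history, best_epoch = best$epoch,
    feature_names = windows$features$variable,
    static_names = setdiff(names(windows$statics), "patient_id"),
    provenance = list(
      seed = config$seed, n_train = n_tr, n_validation = nrow(va),
      train_positives = sum(tr$label),
      data_hash = rlang::hash(list(tr$window_id, tr$label, va$window_id)))
  ), class = "tews_model")
}

#' @export
print.tews_model <- function(x, ...) {
  cat("<tews_model> outcome '", x$outcome, "': ", x$config$n_layers,
      "-layer d=", x$config$d_model, " encoder, trained ",
      nrow(x$history), " epochs (best ", x$best_epoch, "), ",
      x$provenance$n_train, " windows (", x$provenance$train_positives,
      " positive)\n", sep = "")
  invisible(x)
}

#' Predict deterioration risk for windows
#'
#' @param object A `tews_model`.
#' @param windows A `tews_windows` built with the same feature set.
#' @param window_ids Windows to score (default: all eligible for the model's
#'   outcome).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Tibble `window_id`, `patient_id`, `prediction_time`, `label`,
#'   `.pred` (probability in (0, 1)).
#' @export
predict.tews_model <- function(object, windows, window_ids = NULL,
                               batch_size = 512L, ...) {
  stopifnot(inherits(windows, "tews_windows"))
  if (!identical(object$feature_names, windows$features$variable)) {
    stop("feature mismatch: model was trained on (",
         paste(object$feature_names, collapse = ", "), "), windows carry (",
         paste(windows$features$variable, collapse = ", "), ")",
         call. = FALSE)
  }
  frame <- outcome_frame(windows, object$outcome)
  if (!is.null(window_ids)) {
    frame <- frame[frame$window_id %in% window_ids, ]
  }
  cache <- make_tensor_cache(windows)
  pe <- positional_encoding(object$config$t_steps, object$config$d_model)
  pooling <- if (object$config$pooling == "last") 0L else 1L
  preds <- numeric(nrow(frame))
  starts <- seq(1, max(nrow(frame), 1), by = batch_size)
  for (bs in starts) {
    if (nrow(frame) == 0) break
    sel <- bs:min(bs + batch_size - 1, nrow(frame))
    batch <- tensor_batch(cache, match(frame$window_id[sel],
                                       cache$window_ids))
    preds[sel] <- as.numeric(cpp_tews_predict(
      object$params, pe, batch$X, batch$S, object$config$n_layers, pooling,
      batch$first_bin))
  }
  dplyr::mutate(frame, .pred = preds)
}

#' Transfer-learning fine-tune on an external cohort
#'
#' Continues training all parameters of a fitted model on a patient-level
#' fraction of an external cohort, at the same learning rate and one tenth of
#' the original epochs; evaluation is intended for a held-out external
#' partition that must not overlap the fine-tuning sample.
#'
#' @param model A `tews_model`.
#' @param windows External-cohort windows (same feature set).
#' @param fraction Fraction of external patients to fine-tune on, e.g. 0.01
#'   or 0.05; `fraction = 0` returns the model unchanged.
#' @param seed Seed for the patient sample and batch order.
#' @param eval_ids Patient ids reserved for evaluation; sampling is restricted
#'   to the remaining patients and any overlap raises an error.
#' @param epochs Fine-tuning epochs (default `ceiling(model epochs / 10)`).
#' @return A `tews_model` with updated parameters and appended history.
#' @export
fine_tune <- function(model, windows, fraction, seed = 1L,
                      eval_ids = character(0), epochs = NULL) {
  stopifnot(inherits(model, "tews_model"), inherits(windows, "tews_windows"))
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (fraction == 0) return(model)
  if (!identical(model$feature_names, windows$features$variable)) {
    stop("feature mismatch between model and external windows", call. = FALSE)
  }
  pool <- setdiff(unique(windows$index$patient_id), eval_ids)
  if (length(pool) == 0) {
    stop("no patients available outside the evaluation split", call. = FALSE)
  }
  n_take <- max(1L, round(fraction * length(pool)))
  take <- withr::with_seed(seed, sample(pool, n_take))
  if (length(intersect(take, eval_ids)) > 0) {
    stop("fine-tuning sample overlaps the evaluation split", call. = FALSE)
  }
  frame <- outcome_frame(windows, model$outcome)
  frame <- frame[frame$patient_id %in% take, ]
  if (nrow(frame) == 0) stop("fine-tuning sample has no windows",
                             call. = FALSE)

  config <- model$config
  epochs <- epochs %||% max(1L, as.integer(ceiling(config$epochs / 10)))
  cw <- model$class_weights
  cache <- make_tensor_cache(windows)
  pe <- positional_encoding(config$t_steps, config$d_model)
  pooling <- if (config$pooling == "last") 0L else 1L
  state <- list(params = model$params)
  state$m <- lapply(state$params, function(x) x * 0)
  state$v <- state$m
  n_tr <- nrow(frame)
  history <- model$history
  step <- 0L
  withr::with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      for (bs in seq(1, n_tr, by = config$batch_size)) {
        ids <- ord[bs:min(bs + config$batch_size - 1, n_tr)]
        batch <- tensor_batch(cache, match(frame$window_id[ids],
                                           cache$window_ids))
        step <- step + 1L
        res <- cpp_tews_train_batch(
          state$params, pe, batch$X, batch$S, frame$label[ids],
          cw[["pos"]], cw[["neg"]], config$n_layers, pooling,
          batch$first_bin, config$dropout, seed * 1e5 + step,
          tews_constants()$prob_eps)
        if (!is.finite(res$loss)) {
          stop("non-finite fine-tuning loss (epoch ", epoch, ")",
               call. = FALSE)
        }
        state <- adamw_step(state, res$grads, config$learning_rate,
                            config$weight_decay, step)
      }
    }
  })
  out <- model
  out$params <- state$params
  out$provenance$fine_tune <- list(fraction = fraction, seed = seed,
                                   n_patients = n_take, epochs = epochs,
                                   n_windows = n_tr)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted risk model
#'
#' @param x A `tews_model`.
#' @param ... Unused.
#' @return Tibble `epoch`, `train_loss`, `val_loss`.
#' @method tidy tews_model
#' @export
tidy.tews_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `tews_model`.
#' @param ... Unused.
#' @return One-row tibble: outcome, architecture, epochs, best epoch and
#'   losses.
#' @method glance tews_model
#' @export
glance.tews_model <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n_layers = x$config$n_layers,
    d_model = x$config$d_model, n_parameters = sum(lengths(x$params)),
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = if (x$best_epoch > 0 && nrow(x$history) > 0)
      x$history$val_loss[x$best_epoch] else NA_real_,
    final_train_loss = if (nrow(x$history) > 0)
      x$history$train_loss[nrow(x$history)] else NA_real_,
    n_train = x$provenance$n_train,
    train_positives = x$provenance$train_positives)
}

#' Save / load a fitted risk model
#'
#' `save_tews_model()` writes a checkpoint directory: `model.rds` (parameters
#' and training history) plus a human-readable `manifest.json` with the
#' configuration, outcome, feature order, resolved class weights and data
#' hash. `load_tews_model()` reads it back and verifies the manifest matches
#' the parameters.
#'
#' @param model A `tews_model`.
#' @param path Checkpoint directory (created if missing).
#' @return `save_tews_model()` returns `path` invisibly; `load_tews_model()`
#'   returns the `tews_model`.
#' @export
save_tews_model <- function(model, path) {
  stopifnot(inherits(model, "tews_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(path, "model.rds"))
  manifest <- list(
    outcome = model$outcome,
    config = unclass(model$config),
    feature_order = model$feature_names,
    static_order = model$static_names,
    class_weights = as.list(model$class_weights),
    best_epoch = model$best_epoch,
    provenance = model$provenance,
    param_hash = rlang::hash(model$params))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_tews_model
#' @export
load_tews_model <- function(path) {
  model <- readRDS(file.path(path, "model.rds"))
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  if (!identical(manifest$param_hash, rlang::hash(model$params))) {
    stop("checkpoint manifest does not match the stored parameters",
         call. = FALSE)
  }
  if (!identical(unlist(manifest$feature_order), model$feature_names)) {
    stop("checkpoint manifest feature order does not match the model",
         call. = FALSE)
  }
  model
}
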
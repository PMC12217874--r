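# Grad-CAM-style attribution over the (192 x N) input window. The gradient of
# the pre-sigmoid risk score is combined with activations, channel-averaged
# into per-feature weights, rectified (negative contributions zeroed) and
# aggregated over time into a ranked feature list.
#
# Two target layers are available:
#   * "input" (default): gradients taken at the raw input window, so the
#     attribution map is natively at (time x feature) resolution;
#   * "layer": gradients at the final encoder layer's normalised output
#     (the closest analogue of Grad-CAM's last convolutional layer); the
#     time-resolved saliency is projected back onto observed input entries.

#' Grad-CAM attribution maps
#'
#' @param model A fitted `tews_model`.
#' @param windows A `tews_windows` with the model's feature set.
#' @param window_ids Windows to explain (default: all eligible for the model's
#'   outcome).
#' @param mode `"input"` (gradient at the raw window, default) or `"layer"`
#'   (gradient at the last encoder layer, projected back to input resolution).
#' @param batch_size Forward/backward batch size.
#' @return A `tews_saliency`: `maps` (T x N x B nonnegative array),
#'   `aggregate` (B x N matrix of per-feature time sums), an `index` tibble
#'   with the predicted probability, and metadata. All-zero gradients (e.g. a
#'   degenerate zeroed head) yield an all-zero map with a warning.
#' @export
grad_cam <- function(model, windows, window_ids = NULL,
                     mode = c("input", "layer"), batch_size = 256L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "tews_model"), inherits(windows, "tews_windows"))
  if (!identical(model$feature_names, windows$features$variable)) {
    stop("feature mismatch between model and windows", call. = FALSE)
  }
  frame <- outcome_frame(windows, model$outcome)
  if (!is.null(window_ids)) frame <- frame[frame$window_id %in% window_ids, ]
  if (nrow(frame) == 0) stop("no windows to explain", call. = FALSE)

  cache <- make_tensor_cache(windows)
  pe <- positional_encoding(model$config$t_steps, model$config$d_model)
  pooling <- if (model$config$pooling == "last") 0L else 1L
  nt <- model$config$t_steps
  nf <- length(model$feature_names)
  b_all <- nrow(frame)
  maps <- array(0, c(nt, nf, b_all),
                dimnames = list(NULL, model$feature_names, NULL))
  probs <- numeric(b_all)
  n_zero <- 0L
  for (bs in seq(1, b_all, by = batch_size)) {
    sel <- bs:min(bs + batch_size - 1, b_all)
    batch <- tensor_batch(cache, match(frame$window_id[sel],
                                       cache$window_ids))
    res <- cpp_tews_input_grad(model$params, pe, batch$X, batch$S,
                               model$config$n_layers, pooling,
                               batch$first_bin)
    probs[sel] <- as.numeric(res$probs)
    for (j in seq_along(sel)) {
      if (mode == "input") {
        g <- res$dX[, , j]
        if (all(g == 0)) { n_zero <- n_zero + 1L; next }
        alpha <- colMeans(g)                       # channel = feature
        m <- pmax(sweep(batch$X[, , j], 2, alpha, "*"), 0)
      } else {
        g <- res$dHn[, , j]
        if (all(g == 0)) { n_zero <- n_zero + 1L; next }
        alpha <- colMeans(g)                       # channel = d_model dim
        m_t <- pmax(as.numeric(res$Hn[, , j] %*% alpha), 0)
        m <- pmax(batch$X[, , j] * m_t, 0)
      }
      maps[, , sel[j]] <- m
    }
  }
  if (n_zero > 0) {
    warning(n_zero, " window(s) had all-zero gradients; their saliency maps ",
            "are all-zero", call. = FALSE)
  }
  aggregate <- t(apply(maps, 3, colSums))
  if (b_all == 1) aggregate <- matrix(aggregate, 1)
  colnames(aggregate) <- model$feature_names
  structure(list(
    maps = maps, aggregate = aggregate,
    index = dplyr::mutate(frame, .pred = probs),
    features = model$feature_names, mode = mode, outcome = model$outcome
  ), class = "tews_saliency")
}

#' @export
print.tews_saliency <- function(x, ...) {
  cat("<tews_saliency> ", dim(x$maps)[3], " window(s), mode '", x$mode,
      "', outcome '", x$outcome, "'\n", sep = "")
  invisible(x)
}

#' Top contributing features per window
#'
#' Ranks features by their per-window aggregate attribution (sum of rectified
#' saliency over time), descending; ties broken by feature order;
#' zero-attribution features are dropped (an all-zero map yields no rows).
#'
#' @param saliency A [grad_cam()] result.
#' @param k Number of features to keep per window (default 3; values above
#'   the number of features are truncated with a warning).
#' @return Tibble `window_id`, `rank`, `feature`, `weight`.
#' @export
top_features <- function(saliency, k = 3) {
  stopifnot(inherits(saliency, "tews_saliency"))
  nf <- length(saliency$features)
  if (k > nf) {
    warning("k = ", k, " exceeds the number of features (", nf,
            "); truncated", call. = FALSE)
    k <- nf
  }
  out <- lapply(seq_len(nrow(saliency$aggregate)), function(i) {
    w <- saliency$aggregate[i, ]
    ord <- order(-w, seq_along(w))[seq_len(k)]
    ord <- ord[w[ord] > 0]
    if (length(ord) == 0) return(NULL)
    tibble::tibble(window_id = saliency$index$window_id[i],
                   rank = seq_along(ord),
                   feature = saliency$features[ord],
                   weight = unname(w[ord]))
  })
  dplyr::bind_rows(out)
}
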
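# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-history plot
#'
#' Train and validation loss per epoch, with the selected checkpoint marked.
#'
#' @param object A `tews_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tews_model
#' @export
autoplot.tews_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(title = paste0("Weighted BCE, outcome '", object$outcome,
                                 "'"),
                  x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Metric forest plot for an evaluation report
#'
#' Point estimates with bootstrap intervals for each metric.
#'
#' @param object A `tews_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tews_eval
#' @export
autoplot.tews_eval <- function(object, ...) {
  m <- object$metrics
  m$metric <- factor(m$metric, levels = rev(m$metric))
  ggplot2::ggplot(m, ggplot2::aes(.data$estimate, .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(title = paste0("Scorer '", object$scorer, "', threshold ",
                                 signif(object$threshold, 3)),
                  x = "estimate (bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Saliency heatmap for one window
#'
#' Time-by-feature attribution map for a single explained window.
#'
#' @param object A `tews_saliency`.
#' @param window Position (1-based) of the window inside the saliency object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tews_saliency
#' @export
autoplot.tews_saliency <- function(object, window = 1L, ...) {
  m <- object$maps[, , window]
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), bin = dplyr::row_number()),
    -"bin", names_to = "feature", values_to = "saliency")
  df$feature <- factor(df$feature, levels = object$features)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$feature,
                                   fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("Window ", object$index$window_id[window],
                                 " (p = ",
                                 signif(object$index$.pred[window], 3), ")"),
                  x = "15-min bin (1 = 48 h before prediction)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
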
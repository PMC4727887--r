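#' Plot a ROC curve
#'
#' @param object An `frp_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frp_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `frp_cv` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frp_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$contrast, y = .data$value,
    colour = .data$channel_set
  )) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::geom_hline(
      yintercept = ifelse(object$metric[1] == "auc", 0.5, 1 / 3),
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = NULL, y = object$metric[1],
      title = unique(object$scheme)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of the 2-D discriminant projection
#'
#' @param projection Tibble from [export_fda_projection()].
#' @return A ggplot.
#' @export
plot_fda_projection <- function(projection) {
  ggplot2::ggplot(projection, ggplot2::aes(
    x = .data$ld1, y = .data$ld2, colour = .data$label
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Discriminant 1", y = "Discriminant 2",
      title = "Feature vectors on the two leading discriminant axes"
    ) +
    ggplot2::theme_minimal()
}

#' Class-wise grand-average epoch waveforms
#'
#' Averages epochs within each class and plots the fixation-locked time course
#' for one channel.
#'
#' @param epochs An `frp_epochs` object.
#' @param channel Channel name (default `"Pz"`).
#' @return A ggplot.
#' @export
plot_grand_average <- function(epochs, channel = "Pz") {
  ch <- match(channel, epochs$channels$name)
  if (is.na(ch)) abort(paste0("unknown channel: ", channel))
  t_ms <- (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs * 1000
  df <- dplyr::bind_rows(purrr::map(
    unique(epochs$info$label),
    function(cl) {
      idx <- which(epochs$info$label == cl)
      tibble::tibble(
        t_ms = t_ms,
        uV = colMeans(matrix(epochs$data[idx, ch, ], nrow = length(idx))),
        label = cl
      )
    }
  ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$uV, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time after fixation onset (ms)", y = "Amplitude (uV)",
      title = paste0("Grand average at ", channel)
    ) +
    ggplot2::theme_minimal()
}
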
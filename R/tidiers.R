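#' Tidy a fitted PCA model
#'
#' @param x An `frp_pca`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `eigenvalue`,
#'   `prop_variance`, `cum_variance`, `retained`.
#' @exportS3Method generics::tidy
tidy.frp_pca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(
    component = seq_along(ev),
    eigenvalue = ev,
    prop_variance = ev / sum(ev),
    cum_variance = cumsum(ev) / sum(ev),
    retained = seq_along(ev) <= x$k
  )
}

#' @rdname tidy.frp_pca
#' @exportS3Method generics::glance
glance.frp_pca <- function(x, ...) {
  tibble::tibble(
    d = length(x$mean), k = x$k, criterion = x$criterion,
    variance_retained = sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues)
  )
}

#' Tidy a fitted discriminant model
#'
#' @param x An `frp_fda`.
#' @param ... Unused.
#' @return Per-class tibble: `label`, `n`, and the projected class mean on each
#'   discriminant axis.
#' @exportS3Method generics::tidy
tidy.frp_fda <- function(x, ...) {
  mp <- t(x$means_projected)
  colnames(mp) <- paste0("ld", seq_len(ncol(mp)))
  dplyr::bind_cols(
    tibble::tibble(label = x$class_labels, n = x$class_counts),
    tibble::as_tibble(mp)
  )
}

#' @rdname tidy.frp_fda
#' @exportS3Method generics::glance
glance.frp_fda <- function(x, ...) {
  tibble::tibble(
    n = x$n, d = x$d, n_classes = length(x$class_labels),
    lambda = x$lambda, leading_eigenvalue = x$eigenvalues[1]
  )
}

#' Summarise cross-validation results
#'
#' @param x An `frp_cv` tibble.
#' @param ... Unused.
#' @return One row per scheme/contrast/channel set with the mean and SD of the
#'   per-fold (or per-subject) metric.
#' @exportS3Method generics::glance
glance.frp_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(
      tibble::as_tibble(x),
      .data$scheme, .data$contrast, .data$channel_set, .data$metric
    ),
    mean = mean(.data$value), sd = sd(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
}
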
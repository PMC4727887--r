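#' Concatenate channel-wise epochs into feature vectors
#'
#' Appends the per-channel sample blocks of each epoch in fixed channel order,
#' producing one row per epoch of dimension `n_channels x samples_per_epoch`
#' (2460 for 12 EEG channels x 205 samples; 820 for the 4 EOG channels; 3280
#' for all 16).
#'
#' @param epochs An `frp_epochs` object.
#' @param channel_set `"EEG"`, `"EOG"`, `"ALL"`, or a character vector of
#'   channel names (kept in recording order).
#' @return An object of class `frp_features`: `x` (matrix, epochs x d),
#'   `info` (epoch metadata tibble), `channel_names`, `samples_per_epoch`.
#' @export
concatenate_epochs <- function(epochs, channel_set = "EEG") {
  stopifnot(inherits(epochs, "frp_epochs"))
  ch <- epochs$channels
  if (length(channel_set) == 1 && toupper(channel_set) %in% c("EEG", "EOG", "ALL")) {
    set <- toupper(channel_set)
    idx <- if (set == "ALL") seq_len(nrow(ch)) else which(ch$role == set)
  } else {
    idx <- match(channel_set, ch$name)
    if (anyNA(idx)) {
      abort(paste0(
        "unknown channel name(s): ",
        paste(channel_set[is.na(idx)], collapse = ", ")
      ))
    }
    idx <- sort(idx) # recording order
  }
  d <- dim(epochs$data)
  len <- d[3]
  x <- matrix(0, d[1], length(idx) * len)
  for (j in seq_along(idx)) {
    x[, (j - 1) * len + seq_len(len)] <- epochs$data[, idx[j], ]
  }
  structure(
    list(
      x = x, info = epochs$info,
      channel_names = ch$name[idx], samples_per_epoch = len
    ),
    class = "frp_features"
  )
}

#' @export
print.frp_features <- function(x, ...) {
  cat(sprintf(
    "<frp_features> %d vectors in R^%d (%d channels x %d samples)\n",
    nrow(x$x), ncol(x$x), length(x$channel_names), x$samples_per_epoch
  ))
  invisible(x)
}

#' Fit PCA at a fixed explained-variance criterion
#'
#' Mean-centered eigendecomposition of the data covariance, computed via the
#' SVD of the centered data matrix (numerically equivalent, stable for d in the
#' thousands). The retained dimension `k` is the smallest integer such that the
#' leading eigenvalues account for at least `criterion` of the total variance
#' (99.9 % by default). Fit on training data only; apply to held-out data with
#' [predict()].
#'
#' @param x Numeric matrix (observations x d) or an `frp_features` object.
#' @param criterion Explained-variance fraction in (0, 1].
#' @return An object of class `frp_pca`: `mean`, `rotation` (d x k, orthonormal
#'   columns), `eigenvalues` (all, descending), `k`, `criterion`.
#' @export
fit_pca <- function(x, criterion = 0.999) {
  if (inherits(x, "frp_features")) x <- x$x
  stopifnot(is.matrix(x), criterion > 0, criterion <= 1)
  n <- nrow(x)
  if (n < 2) abort("PCA needs at least 2 training vectors")
  mu <- colMeans(x)
  sv <- svd(sweep(x, 2, mu))
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total == 0) abort("training data has zero variance")
  rank <- sum(ev > max(ev) * 1e-12)
  k <- if (criterion >= 1) rank else min(which(cumsum(ev) / total >= criterion))
  structure(
    list(
      mean = mu,
      rotation = sv$v[, seq_len(k), drop = FALSE],
      eigenvalues = ev,
      k = k,
      criterion = criterion
    ),
    class = "frp_pca"
  )
}

#' @export
print.frp_pca <- function(x, ...) {
  cat(sprintf(
    "<frp_pca> k = %d of %d dims (criterion %.4g, retained %.4f of variance)\n",
    x$k, length(x$mean), x$criterion,
    sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues)
  ))
  invisible(x)
}

#' Project data onto a fitted PCA basis
#'
#' @param object An `frp_pca` model.
#' @param newdata Matrix (observations x d), a single length-d vector, or an
#'   `frp_features` object.
#' @param ... Unused.
#' @return Matrix of k-dimensional projected coordinates.
#' @export
predict.frp_pca <- function(object, newdata, ...) {
  if (inherits(newdata, "frp_features")) newdata <- newdata$x
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$mean)) {
    abort(sprintf(
      "feature length mismatch: model expects %d, got %d",
      length(object$mean), ncol(newdata)
    ))
  }
  sweep(newdata, 2, object$mean) %*% object$rotation
}
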
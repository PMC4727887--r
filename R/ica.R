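#' Fit an Infomax ICA decomposition on the EEG channels
#'
#' Batch natural-gradient Infomax with a logistic nonlinearity, the classic
#' algorithm for separating ocular sources from EEG. Channels are centered and
#' whitened (eigendecomposition of the channel covariance), then the square
#' unmixing matrix is learned by full-batch natural-gradient ascent on the
#' Infomax objective with annealed learning rate. Components are normalised to
#' unit activation variance, ordered by back-projected power, and sign-fixed
#' (largest-magnitude mixing entry positive) so the decomposition is
#' reproducible. Only channels with role `"EEG"` enter the decomposition.
#'
#' Intended use is decomposition of *training* data: the fitted model is frozen
#' and applied unchanged to held-out data.
#'
#' @param recording An `frp_recording`.
#' @param seed Integer seed for the random orthogonal initialisation.
#' @param max_iter Maximum number of batch iterations.
#' @param tol Relative weight-change convergence tolerance.
#' @return An object of class `frp_ica`: `unmixing` (components x channels),
#'   `mixing` (channels x components), `center`, `channel_names`, `n_iter`.
#' @export
fit_ica <- function(recording, seed = 1, max_iter = 1000, tol = 1e-7) {
  stopifnot(inherits(recording, "frp_recording"))
  eeg <- recording$channels$role == "EEG"
  x <- recording$data[eeg, , drop = FALSE]
  n_ch <- nrow(x)
  n <- ncol(x)
  if (n <= 20 * n_ch^2) {
    warn(sprintf(
      "ICA on %d samples for %d channels; > %d samples recommended for stability",
      n, n_ch, 20 * n_ch^2
    ))
  }
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / (n - 1)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values)) {
    abort("recording is rank-deficient; ICA requires full-rank EEG data")
  }
  whitener <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  z <- whitener %*% xc

  set.seed(seed)
  w <- qr.Q(qr(matrix(rnorm(n_ch^2), n_ch))) # random orthogonal init
  lr <- 0.05
  old_delta <- NULL
  for (iter in seq_len(max_iter)) {
    u <- w %*% z
    y <- 1 / (1 + exp(-u))
    grad <- (diag(n_ch) + ((1 - 2 * y) %*% t(u)) / n) %*% w
    delta <- lr * grad
    if (any(!is.finite(delta))) {
      lr <- lr / 2
      next
    }
    w <- w + delta
    if (!is.null(old_delta)) {
      # anneal when the update direction swings by more than 60 degrees
      ang <- sum(delta * old_delta) /
        sqrt(sum(delta^2) * sum(old_delta^2) + 1e-300)
      if (ang < 0.5) lr <- lr * 0.9
    }
    old_delta <- delta
    if (sqrt(sum(delta^2)) < tol * sqrt(sum(w^2))) break
  }

  unmixing <- w %*% whitener
  act_sd <- sqrt(rowSums((unmixing %*% xc)^2) / (n - 1))
  unmixing <- unmixing / act_sd
  mixing <- solve(unmixing)
  # order components by back-projected power, fix signs
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  flip <- sign(mixing[cbind(apply(abs(mixing), 2, which.max), seq_len(n_ch))])
  unmixing <- unmixing * flip
  mixing <- mixing * rep(flip, each = n_ch)

  structure(
    list(
      unmixing = unmixing, mixing = mixing, center = center,
      channel_names = recording$channels$name[eeg], n_iter = iter
    ),
    class = "frp_ica"
  )
}

#' @export
print.frp_ica <- function(x, ...) {
  cat(sprintf(
    "<frp_ica> %d components over %d EEG channels (%d iterations)\n",
    nrow(x$unmixing), ncol(x$unmixing), x$n_iter
  ))
  invisible(x)
}

#' Component activation time-courses
#'
#' @param model An `frp_ica` model.
#' @param recording An `frp_recording` with the same EEG channels.
#' @return Matrix, components x samples.
#' @export
ica_activations <- function(model, recording) {
  stopifnot(inherits(model, "frp_ica"), inherits(recording, "frp_recording"))
  idx <- match(model$channel_names, recording$channels$name)
  if (anyNA(idx)) abort("recording lacks the channels the ICA was fitted on")
  model$unmixing %*% (recording$data[idx, , drop = FALSE] - model$center)
}

#' Flag ocular-artifact components by EOG correlation
#'
#' Automated replacement for visual scalp-map inspection: a component is
#' flagged when the absolute Pearson correlation of its activation time-course
#' with any EOG channel reaches `corr_threshold`.
#'
#' @param model An `frp_ica` model.
#' @param recording An `frp_recording` containing EOG channels.
#' @param corr_threshold Absolute-correlation threshold in (0, 1].
#' @return Integer vector of flagged component indices (possibly empty).
#' @export
select_artifact_components <- function(model, recording, corr_threshold = 0.7) {
  stopifnot(inherits(recording, "frp_recording"))
  eog <- recording$data[recording$channels$role == "EOG", , drop = FALSE]
  if (nrow(eog) == 0) abort("recording contains no EOG channels")
  act <- ica_activations(model, recording)
  cc <- abs(cor(t(act), t(eog)))
  which(apply(cc, 1, max) >= corr_threshold - 1e-12)
}

#' Remove ICA components from a recording
#'
#' Back-projects the EEG channels with the flagged components zeroed; EOG
#' channels are left untouched.
#'
#' @param recording An `frp_recording`.
#' @param model An `frp_ica` model fitted on the same EEG montage.
#' @param indices Component indices to remove (possibly empty).
#' @return A cleaned `frp_recording`.
#' @export
remove_components <- function(recording, model, indices) {
  stopifnot(inherits(recording, "frp_recording"), inherits(model, "frp_ica"))
  k <- nrow(model$unmixing)
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1 || max(indices) > k)) {
    abort(sprintf("component indices must lie in 1..%d", k))
  }
  idx <- match(model$channel_names, recording$channels$name)
  act <- ica_activations(model, recording)
  keep <- setdiff(seq_len(k), indices)
  clean <- model$mixing[, keep, drop = FALSE] %*% act[keep, , drop = FALSE] +
    model$center
  out <- recording
  out$data[idx, ] <- clean
  out
}
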
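#' Extract fixation-locked epochs
#'
#' One epoch per fixation, starting at the first EEG sample of the fixation and
#' lasting `epoch_ms` (default 800 ms, i.e. `round(0.8 * fs)` samples per
#' channel — 205 at 256 Hz). Fixations whose window would run past the end of
#' the recording are dropped with a warning.
#'
#' @param recording An `frp_recording`.
#' @param fixations Labelled fixation tibble ([label_fixations()]).
#' @param epoch_ms Epoch length, ms.
#' @param subject_id Optional subject identifier stored with each epoch.
#' @return An object of class `frp_epochs`: `data` (array, epochs x channels x
#'   samples, microvolts), `info` (tibble: `epoch`, `onset_sample`, `label`,
#'   `subject_id`), `fs`, `channels`.
#' @export
extract_epochs <- function(recording, fixations, epoch_ms = 800,
                           subject_id = NA_integer_) {
  stopifnot(inherits(recording, "frp_recording"))
  fs <- recording$fs
  len <- round(epoch_ms / 1000 * fs)
  onset <- round(fixations$onset_ms / 1000 * fs) + 1L
  ok <- onset + len - 1L <= ncol(recording$data) & onset >= 1L
  if (any(!ok)) {
    warn(sprintf(
      "dropping %d fixation(s) whose %g ms window exceeds the recording",
      sum(!ok), epoch_ms
    ))
  }
  onset <- onset[ok]
  n <- length(onset)
  n_ch <- nrow(recording$data)
  data <- array(0, dim = c(n, n_ch, len))
  for (i in seq_len(n)) {
    data[i, , ] <- recording$data[, onset[i]:(onset[i] + len - 1L)]
  }
  structure(
    list(
      data = data,
      info = tibble::tibble(
        epoch = seq_len(n),
        onset_sample = onset,
        label = fixations$label[ok],
        subject_id = subject_id
      ),
      fs = fs,
      channels = recording$channels
    ),
    class = "frp_epochs"
  )
}

#' @export
print.frp_epochs <- function(x, ...) {
  cat(sprintf(
    "<frp_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs
  ))
  print(table(x$info$label))
  invisible(x)
}

#' Zero-phase band-pass filter epochs
#'
#' Filters every channel of every epoch with cut-offs `lo`-`hi` Hz, zero phase
#' (forward-backward) so component latencies are preserved. The low-pass side
#' is a Butterworth filter run in both directions with steady-state initial
#' conditions and reflection padding. The high-pass side depends on the window
#' length: an IIR high-pass at 0.5 Hz rings far beyond an 800 ms window, so on
#' windows shorter than one period of `lo` the sub-`lo` content — which such a
#' window can only express as its mean and a linear ramp — is removed by
#' endpoint-matched detrending plus demeaning; longer windows get the true
#' zero-phase Butterworth high-pass. Both realisations are linear.
#'
#' @param epochs An `frp_epochs` object.
#' @param lo,hi Cut-off frequencies, Hz (`0 < lo < hi < fs/2`).
#' @param order Butterworth prototype order.
#' @return The filtered `frp_epochs`.
#' @export
bandpass_epochs <- function(epochs, lo = 0.5, hi = 10, order = 4) {
  stopifnot(inherits(epochs, "frp_epochs"))
  fs <- epochs$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    abort("invalid cutoffs: need 0 < lo < hi < fs/2")
  }
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  d <- dim(epochs$data)
  short <- d[3] < fs / lo
  hp <- if (!short) signal::butter(order, lo / (fs / 2), type = "high")
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[i, ch, ]
      x <- if (short) detrend_ols(x) else filtfilt_ss(hp$b, hp$a, x)
      epochs$data[i, ch, ] <- filtfilt_ss(lp$b, lp$a, x)
    }
  }
  epochs
}

# least-squares removal of mean and linear trend: the drift terms a
# sub-period window can express
detrend_ols <- function(x) {
  n <- length(x)
  tt <- seq_len(n) - (n + 1) / 2
  x - mean(x) - tt * sum(tt * x) / sum(tt^2)
}

# zero-phase IIR filtering with steady-state initial conditions and
# odd-reflection padding
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  pad <- n - 1L
  xp <- c(
    2 * x[1] - x[(pad + 1):2],
    x,
    2 * x[n] - x[(n - 1):(n - pad)]
  )
  fwd <- iir_df1(b, a, xp)
  bwd <- rev(iir_df1(b, a, rev(fwd)))
  bwd[(pad + 1):(pad + n)]
}

# direct-form-I IIR filter initialised at the steady state for a constant
# input equal to the first sample
iir_df1 <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  x0 <- x[1]
  y0 <- x0 * sum(b) / sum(a) # DC steady-state output
  w <- stats::filter(c(rep(x0, nb - 1), x), b, method = "convolution", sides = 1)
  w <- as.numeric(w)[(nb - 1) + seq_along(x)]
  if (na > 1) {
    y <- stats::filter(w, -a[-1], method = "recursive", init = rep(y0, na - 1))
    as.numeric(y)
  } else {
    w
  }
}
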
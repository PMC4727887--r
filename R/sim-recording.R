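#' Construct a multi-channel recording object
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate, Hz.
#' @param channels Tibble with columns `name`, `role` (one row per data row).
#' @return An object of class `frp_recording`.
#' @export
new_recording <- function(data, fs, channels = frp_channels()) {
  stopifnot(is.matrix(data), nrow(data) == nrow(channels), fs > 0)
  rownames(data) <- channels$name
  structure(list(data = data, fs = fs, channels = channels),
    class = "frp_recording"
  )
}

#' @export
print.frp_recording <- function(x, ...) {
  cat(sprintf(
    "<frp_recording> %d channels (%d EEG, %d EOG) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), sum(x$channels$role == "EEG"), sum(x$channels$role == "EOG"),
    ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' Simulate the EEG/EOG recording for a ground-truth fixation sequence
#'
#' Per channel the signal is the sum of (i) AR(1) background noise with
#' stationary SD `noise_sd_uv`, (ii) for every fixation a Gaussian-windowed
#' positive deflection of the class-specific amplitude, peaking
#' `frp_peak_latency_ms` after fixation onset and scaled by the per-channel
#' `topography` gain (EEG channels only), and (iii) a saccade-locked pulse
#' whose amplitude is proportional to the saccade size in degrees, scaled by
#' `eog_artifact_gain` (predominantly EOG/frontal). Units are microvolts.
#'
#' @param truth Ground-truth tibble from [simulate_scanpath()] /
#'   [simulate_session()].
#' @param config An [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param duration_ms Total recording length; defaults to the last fixation
#'   onset plus 1.5 s so that every 800 ms epoch fits.
#' @return An `frp_recording` (16 channels at `fs_eeg`).
#' @export
simulate_recording <- function(truth, config, seed = config$seed,
                               duration_ms = NULL) {
  stopifnot(inherits(config, "frp_sim_config"))
  if (is.null(truth) || nrow(truth) == 0) {
    abort("cannot simulate a recording from empty ground truth")
  }
  set.seed(seed)
  fs <- config$fs_eeg
  duration_ms <- duration_ms %||% (max(truth$onset_ms) + 1500)
  n <- ceiling(duration_ms / 1000 * fs)
  chans <- frp_channels()
  n_ch <- nrow(chans)
  t_ms <- (seq_len(n) - 1) / fs * 1000

  # AR(1) noise, innovations scaled for stationary sd = noise_sd_uv
  data <- matrix(0, n_ch, n, dimnames = list(chans$name, NULL))
  if (config$noise_sd_uv > 0) {
    innov_sd <- config$noise_sd_uv * sqrt(1 - config$noise_ar^2)
    for (ch in seq_len(n_ch)) {
      data[ch, ] <- as.numeric(stats::filter(
        rnorm(n, 0, innov_sd),
        config$noise_ar,
        method = "recursive"
      ))
    }
  }

  # fixation-locked component on EEG channels
  topo <- c(config$topography, rep(0, 4))
  amp <- config$frp_amplitude_uv[truth$label]
  for (i in seq_len(nrow(truth))) {
    if (amp[i] == 0) next
    frp <- frp_waveform(t_ms, truth$onset_ms[i], amp[i], config)
    nz <- which(frp != 0)
    if (length(nz)) data[, nz] <- data[, nz] + topo %o% frp[nz]
  }

  # saccade-locked corneo-retinal artifact; one pulse per inter-fixation move
  if (any(config$eog_artifact_gain != 0) && nrow(truth) > 1) {
    gain <- config$eog_artifact_gain[chans$name]
    dx <- diff(truth$cx_px)
    dy <- diff(truth$cy_px)
    amp_deg <- sqrt(dx^2 + dy^2) / config$px_per_deg
    mid_ms <- truth$onset_ms[-1] - config$saccade_duration_ms / 2
    for (i in seq_along(mid_ms)) {
      pulse <- gauss_pulse(t_ms, mid_ms[i], sd_ms = 8)
      nz <- which(pulse != 0)
      if (length(nz)) data[, nz] <- data[, nz] + (gain * amp_deg[i]) %o% pulse[nz]
    }
  }

  rec <- new_recording(data, fs, chans)
  attr(rec, "frp_onsets") <- pmin(n, round(truth$onset_ms / 1000 * fs) + 1L)
  rec
}

# class-amplitude Gaussian deflection; zero outside +/- 4 SD for speed
frp_waveform <- function(t_ms, onset_ms, amplitude, config) {
  peak <- onset_ms + config$frp_peak_latency_ms
  w <- config$frp_width_ms
  out <- numeric(length(t_ms))
  win <- t_ms >= peak - 4 * w & t_ms <= peak + 4 * w
  out[win] <- amplitude * exp(-((t_ms[win] - peak)^2) / (2 * w^2))
  out
}

gauss_pulse <- function(t_ms, center_ms, sd_ms) {
  out <- numeric(length(t_ms))
  win <- t_ms >= center_ms - 4 * sd_ms & t_ms <= center_ms + 4 * sd_ms
  out[win] <- exp(-((t_ms[win] - center_ms)^2) / (2 * sd_ms^2))
  out
}

#' Simulate a complete multi-subject dataset
#'
#' Runs [simulate_session()] and [simulate_recording()] once per subject, with
#' per-subject seeds derived deterministically from `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A list of length `n_subjects`; each element has `subject_id`,
#'   `layout`, `gaze`, `truth`, `recording`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "frp_sim_config"))
  purrr::map(seq_len(config$n_subjects), function(s) {
    seed_s <- config$seed + 104729L * s
    sess <- simulate_session(config, seed = seed_s)
    rec <- simulate_recording(sess$truth, config, seed = seed_s + 1L)
    list(
      subject_id = s, layout = sess$layout, gaze = sess$gaze,
      truth = sess$truth, recording = rec
    )
  })
}
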
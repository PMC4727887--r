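#' Reference channel montage
#'
#' The 16-channel montage assumed throughout the package: twelve EEG channels
#' (Fz, F3, F4, Cz, C3, C4, Pz, P3, P4, PO7, PO8, Oz, mastoid-referenced) and
#' four EOG channels registering the corneo-retinal standing potential (two
#' vertical, above/below the right eye; two horizontal, beside each eye).
#'
#' @return A tibble with columns `name` and `role` (`"EEG"` or `"EOG"`).
#' @export
#' @examples
#' frp_channels()
frp_channels <- function() {
  tibble::tibble(
    name = c(
      "Fz", "F3", "F4", "Cz", "C3", "C4",
      "Pz", "P3", "P4", "PO7", "PO8", "Oz",
      "VEOGu", "VEOGl", "HEOGl", "HEOGr"
    ),
    role = c(rep("EEG", 12), rep("EOG", 4))
  )
}

#' Simulation configuration for co-registered gaze + EEG data
#'
#' Bundles every tunable parameter of the synthetic-data generator. Defaults
#' describe a visual-search session over a 4 x 3 grid of objects viewed through
#' a gaze-contingent keyhole: per-class fixation durations with the means and
#' SDs observed in such tasks (target 270 +/- 38 ms, non-target 281 +/- 37 ms,
#' background 241 +/- 29 ms), a parieto-central positive FRP component that is
#' strong for target fixations and weak otherwise, AR(1) background EEG noise,
#' and saccade-locked ocular artifacts projected predominantly onto the EOG and
#' frontal channels.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_trials Search trials per subject; each trial is a scanpath that
#'   visits non-target objects (with occasional background fixations) until the
#'   target is found and dwelt on.
#' @param fs_eeg EEG/EOG sampling rate, Hz. 256 Hz makes an 800 ms epoch
#'   exactly `round(0.8 * 256) = 205` samples long.
#' @param fs_gaze Gaze sampling rate, Hz (120 Hz class remote tracker).
#' @param screen_px Screen size, `c(width, height)` in pixels.
#' @param px_per_deg Pixels per degree of visual angle (40 makes 2.5 deg
#'   approximately 100 px).
#' @param fix_duration_means_ms,fix_duration_sds_ms Named numeric vectors
#'   (`target`, `nontarget`, `background`): per-class fixation-duration means
#'   and SDs, ms. Durations are drawn from a normal truncated below at
#'   `duration_floor_ms`.
#' @param duration_floor_ms Lower truncation bound for fixation durations, ms;
#'   equals the temporal detection threshold so every generated fixation is
#'   detectable.
#' @param frp_amplitude_uv Named per-class peak amplitude (microvolts) of the
#'   fixation-locked component.
#' @param frp_peak_latency_ms Latency of the component peak after fixation
#'   onset, ms.
#' @param frp_width_ms Temporal width (Gaussian SD) of the component, ms.
#' @param topography Per-EEG-channel gain of the FRP component (length 12,
#'   order of [frp_channels()]); default is parieto-central (Pz/Cz largest).
#' @param noise_sd_uv Background noise SD per channel, microvolts.
#' @param noise_ar AR(1) coefficient of the background noise (spectrally
#'   1/f-like for values near 1).
#' @param eog_artifact_gain Per-channel gain (length 16, microvolts per degree
#'   of saccade amplitude) of the saccade-locked corneo-retinal artifact.
#' @param saccade_duration_ms Saccade flight time between fixations, ms.
#' @param gaze_jitter_deg SD of within-fixation gaze jitter, degrees; must stay
#'   well below the detection dispersion.
#' @param object_radius_deg Radius of an object for onto-object labelling,
#'   degrees.
#' @param grid_jitter_deg SD of the random offset applied to grid positions,
#'   degrees.
#' @param p_background Probability of inserting a background fixation between
#'   consecutive object visits.
#' @param n_target_dwell Consecutive fixations on the target once found.
#' @param trial_gap_ms Gap between trials, ms.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#'
#' @return An object of class `frp_sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 5, seed = 1)
#' cfg$fs_eeg
sim_config <- function(n_subjects = 1,
                       n_trials = 30,
                       fs_eeg = 256,
                       fs_gaze = 120,
                       screen_px = c(1680, 1050),
                       px_per_deg = 40,
                       fix_duration_means_ms = c(target = 270, nontarget = 281, background = 241),
                       fix_duration_sds_ms = c(target = 38, nontarget = 37, background = 29),
                       duration_floor_ms = 60,
                       frp_amplitude_uv = c(target = 8, nontarget = 1, background = 1),
                       frp_peak_latency_ms = 400,
                       frp_width_ms = 70,
                       topography = c(
                         Fz = 0.5, F3 = 0.4, F4 = 0.4, Cz = 0.9, C3 = 0.6, C4 = 0.6,
                         Pz = 1.0, P3 = 0.8, P4 = 0.8, PO7 = 0.5, PO8 = 0.5, Oz = 0.6
                       ),
                       noise_sd_uv = 10,
                       noise_ar = 0.95,
                       eog_artifact_gain = c(
                         Fz = 1.0, F3 = 0.9, F4 = 0.9, Cz = 0.25, C3 = 0.2, C4 = 0.2,
                         Pz = 0.08, P3 = 0.06, P4 = 0.06, PO7 = 0.05, PO8 = 0.05, Oz = 0.05,
                         VEOGu = 10, VEOGl = -8, HEOGl = 9, HEOGr = -9
                       ),
                       saccade_duration_ms = 30,
                       gaze_jitter_deg = 0.15,
                       object_radius_deg = 2.5,
                       grid_jitter_deg = 0.5,
                       p_background = 0.25,
                       n_target_dwell = 2,
                       trial_gap_ms = 500,
                       seed = 1L) {
  classes <- c("target", "nontarget", "background")
  fix_duration_means_ms <- fix_duration_means_ms[classes]
  fix_duration_sds_ms <- fix_duration_sds_ms[classes]
  frp_amplitude_uv <- frp_amplitude_uv[classes]

  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    fs_eeg = fs_eeg, fs_gaze = fs_gaze, screen_px = screen_px,
    px_per_deg = px_per_deg,
    fix_duration_means_ms = fix_duration_means_ms,
    fix_duration_sds_ms = fix_duration_sds_ms,
    duration_floor_ms = duration_floor_ms,
    frp_amplitude_uv = frp_amplitude_uv,
    frp_peak_latency_ms = frp_peak_latency_ms,
    frp_width_ms = frp_width_ms,
    topography = topography,
    noise_sd_uv = noise_sd_uv, noise_ar = noise_ar,
    eog_artifact_gain = eog_artifact_gain,
    saccade_duration_ms = saccade_duration_ms,
    gaze_jitter_deg = gaze_jitter_deg,
    object_radius_deg = object_radius_deg,
    grid_jitter_deg = grid_jitter_deg,
    p_background = p_background,
    n_target_dwell = as.integer(n_target_dwell),
    trial_gap_ms = trial_gap_ms,
    seed = as.integer(seed)
  )
  class(cfg) <- "frp_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "frp_sim_config"))
  if (any(cfg$fix_duration_means_ms <= 0) || any(cfg$fix_duration_sds_ms < 0)) {
    abort("fixation duration means must be > 0 and SDs >= 0")
  }
  if (cfg$fs_eeg <= 0 || cfg$fs_gaze <= 0) {
    abort("sampling rates must be positive")
  }
  if (length(cfg$topography) != 12L) {
    abort("topography must have one gain per EEG channel (12)")
  }
  if (length(cfg$eog_artifact_gain) != 16L) {
    abort("eog_artifact_gain must have one gain per channel (16)")
  }
  if (any(cfg$fix_duration_means_ms < cfg$duration_floor_ms)) {
    abort(paste0(
      "every fixation duration mean must be >= the temporal detection floor (",
      cfg$duration_floor_ms, " ms); shorter fixations would be undetectable"
    ))
  }
  amp <- cfg$frp_amplitude_uv
  if (!(amp["target"] >= amp["nontarget"] && amp["nontarget"] >= amp["background"])) {
    warn("frp_amplitude_uv does not follow the target >= nontarget >= background effect direction")
  }
  invisible(cfg)
}

#' @export
print.frp_sim_config <- function(x, ...) {
  cat("<frp_sim_config>\n")
  cat(sprintf(
    "  %d subject(s) x %d trial(s); fs_eeg %g Hz, fs_gaze %g Hz, %g px/deg\n",
    x$n_subjects, x$n_trials, x$fs_eeg, x$fs_gaze, x$px_per_deg
  ))
  cat(sprintf(
    "  fixation means (ms): target %g, nontarget %g, background %g\n",
    x$fix_duration_means_ms[1], x$fix_duration_means_ms[2], x$fix_duration_means_ms[3]
  ))
  cat(sprintf(
    "  FRP peak (uV): target %g, nontarget %g, background %g at %g ms\n",
    x$frp_amplitude_uv[1], x$frp_amplitude_uv[2], x$frp_amplitude_uv[3],
    x$frp_peak_latency_ms
  ))
  invisible(x)
}

# draws from N(mean, sd) truncated below at `lower`; vectorised over n
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) {
    return(rep(max(mean, lower), n))
  }
  # inverse-CDF sampling restricted to [lower, Inf)
  p_lo <- pnorm(lower, mean, sd)
  u <- runif(n, p_lo, 1)
  qnorm(u, mean, sd)
}
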
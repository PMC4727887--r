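# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# a default-condition subject used by several detection/feature tests
ref_subject <- function() {
  if (is.null(.fixtures$subj)) {
    cfg <- sim_config(n_trials = 12, seed = 42)
    .fixtures$cfg <- cfg
    .fixtures$subj <- simulate_dataset(cfg)[[1]]
  }
  .fixtures$subj
}

ref_config <- function() {
  invisible(ref_subject())
  .fixtures$cfg
}

# labelled epochs for the reference subject (detection -> labelling -> epochs)
ref_epochs <- function() {
  if (is.null(.fixtures$epochs)) {
    subj <- ref_subject()
    fx <- detect_fixations(subj$gaze, px_per_deg = 40)
    fx <- label_fixations(fx, subj$layout)
    .fixtures$epochs <- extract_epochs(subj$recording, fx, subject_id = 1L)
  }
  .fixtures$epochs
}

# minimal epochs object around a bare array, for filter tests
make_epochs <- function(data, fs = 256) {
  if (length(dim(data)) != 3) data <- array(data, c(1, 1, length(data)))
  n_ch <- dim(data)[2]
  structure(
    list(
      data = data,
      info = tibble::tibble(
        epoch = seq_len(dim(data)[1]),
        onset_sample = 1L,
        label = "unlabelled",
        subject_id = 1L
      ),
      fs = fs,
      channels = tibble::tibble(
        name = frp_channels()$name[seq_len(n_ch)],
        role = frp_channels()$role[seq_len(n_ch)]
      )
    ),
    class = "frp_epochs"
  )
}

# stationary gaze stream helper
gaze_at <- function(x, y, n, fs = 120, t0 = 0, valid = TRUE) {
  g <- tibble::tibble(
    t_ms = t0 + (seq_len(n) - 1) * 1000 / fs,
    x_px = rep_len(x, n),
    y_px = rep_len(y, n),
    valid = rep_len(valid, n)
  )
  attr(g, "fs_gaze") <- fs
  g
}

# rank-based (Mann-Whitney) AUC oracle, independent of the threshold sweep
rank_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# small null subject: no FRP, no artifacts -> labels carry no information
null_epochs <- function(seed = 101, n_trials = 22) {
  cfg <- sim_config(
    n_trials = n_trials, seed = seed,
    frp_amplitude_uv = c(target = 0, nontarget = 0, background = 0),
    eog_artifact_gain = setNames(rep(0, 16), frp_channels()$name)
  )
  subj <- simulate_dataset(cfg)[[1]]
  fx <- label_fixations(
    detect_fixations(subj$gaze, px_per_deg = 40), subj$layout
  )
  bandpass_epochs(extract_epochs(subj$recording, fx, subject_id = 1L))
}

# high-SNR subject from the calibrated reference configuration
high_snr_epochs <- function(seed = 202, n_trials = 30, scramble_topo = FALSE,
                            subject_id = 1L) {
  topo <- c(
    Fz = 0.5, F3 = 0.4, F4 = 0.4, Cz = 0.9, C3 = 0.6, C4 = 0.6,
    Pz = 1.0, P3 = 0.8, P4 = 0.8, PO7 = 0.5, PO8 = 0.5, Oz = 0.6
  )
  if (scramble_topo) {
    set.seed(seed + 5000L)
    names(topo) <- names(topo)[sample(12)]
    topo <- topo[c(
      "Fz", "F3", "F4", "Cz", "C3", "C4",
      "Pz", "P3", "P4", "PO7", "PO8", "Oz"
    )]
  }
  cfg <- sim_config(
    n_trials = n_trials, seed = seed,
    frp_amplitude_uv = c(target = 16, nontarget = 1, background = 1),
    topography = topo
  )
  subj <- simulate_dataset(cfg)[[1]]
  fx <- label_fixations(
    detect_fixations(subj$gaze, px_per_deg = 40), subj$layout
  )
  bandpass_epochs(extract_epochs(subj$recording, fx, subject_id = subject_id))
}

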
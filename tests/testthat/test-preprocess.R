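two_channel_rec <- function(data) {
  new_recording(data, fs = 256, channels = tibble::tibble(
    name = c("Fz", "Cz"), role = "EEG"
  ))
}

test_that("Infomax recovers two mixed super-Gaussian sources", {
  set.seed(1)
  n <- 20000
  s <- rbind(
    sign(runif(n) - 0.5) * rexp(n),
    sign(runif(n) - 0.5) * rexp(n)
  )
  mixing <- matrix(c(1, 0.6, 0.4, 1), 2)
  rec <- two_channel_rec(mixing %*% s)
  model <- fit_ica(rec, seed = 3)
  cc <- abs(cor(t(ica_activations(model, rec)), t(s)))
  # each true source matched by some component up to permutation/scale
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  expect_false(which.max(cc[, 1]) == which.max(cc[, 2]))
})

test_that("identity mixing yields a scaled permutation of the identity", {
  set.seed(2)
  n <- 20000
  s <- rbind(
    sign(runif(n) - 0.5) * rexp(n),
    sign(runif(n) - 0.5) * rexp(n)
  )
  rec <- two_channel_rec(s)
  model <- fit_ica(rec, seed = 3)
  w <- abs(model$unmixing)
  w <- w / apply(w, 1, max)
  # one dominant entry per row, in distinct columns
  expect_true(all(apply(w, 1, sort)[1, ] < 0.2))
  expect_equal(sort(apply(w, 1, which.max)), 1:2)
})

test_that("ICA is deterministic given data and seed", {
  set.seed(4)
  n <- 8000
  s <- rbind(sign(runif(n) - 0.5) * rexp(n), sign(runif(n) - 0.5) * rexp(n))
  rec <- two_channel_rec(matrix(c(1, 0.3, 0.5, 1), 2) %*% s)
  m1 <- fit_ica(rec, seed = 11)
  m2 <- fit_ica(rec, seed = 11)
  expect_identical(m1$unmixing, m2$unmixing)
  expect_identical(m1$mixing, m2$mixing)
})

strong_artifact_config <- function(seed = 11) {
  sim_config(
    n_trials = 20, seed = seed, noise_sd_uv = 5,
    eog_artifact_gain = c(
      Fz = 8, F3 = 7, F4 = 7, Cz = 2, C3 = 1.5, C4 = 1.5,
      Pz = 0.5, P3 = 0.4, P4 = 0.4, PO7 = 0.3, PO8 = 0.3, Oz = 0.3,
      VEOGu = 10, VEOGl = -8, HEOGl = 9, HEOGr = -9
    )
  )
}

test_that("components mirroring the EOG are flagged; exact-copy boundary works", {
  cfg <- strong_artifact_config()
  sess <- simulate_session(cfg)
  rec <- simulate_recording(sess$truth, cfg)
  model <- fit_ica(rec, seed = 2)
  sel <- select_artifact_components(model, rec, corr_threshold = 0.7)
  expect_gte(length(sel), 1)

  # a recording whose first EEG channel is an exact copy of VEOGu: with an
  # identity-like decomposition only the exact-copy component survives
  # threshold 1.0
  set.seed(5)
  n <- 6000
  eog <- matrix(rnorm(4 * n), 4)
  eeg <- rbind(eog[1, ], matrix(rnorm(n), 1))
  chans <- tibble::tibble(
    name = c("Fz", "Cz", "VEOGu", "VEOGl", "HEOGl", "HEOGr"),
    role = c("EEG", "EEG", rep("EOG", 4))
  )
  rec2 <- new_recording(rbind(eeg, eog), fs = 256, channels = chans)
  m2 <- fit_ica(rec2, seed = 1)
  sel_strict <- select_artifact_components(m2, rec2, corr_threshold = 1.0)
  cc <- abs(cor(t(ica_activations(m2, rec2)), t(eog)))
  expect_equal(sel_strict, which(apply(cc, 1, max) >= 1 - 1e-12))
  expect_gte(length(select_artifact_components(m2, rec2, 0.7)), 1)
})

test_that("artifact-free recordings yield an empty component selection", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 4000
    eeg <- matrix(rnorm(2 * n), 2)
    eog <- matrix(rnorm(4 * n), 4)
    chans <- tibble::tibble(
      name = c("Fz", "Cz", "VEOGu", "VEOGl", "HEOGl", "HEOGr"),
      role = c("EEG", "EEG", rep("EOG", 4))
    )
    rec <- new_recording(rbind(eeg, eog), fs = 256, channels = chans)
    model <- suppressWarnings(fit_ica(rec, seed = seed))
    length(select_artifact_components(model, rec, corr_threshold = 0.7))
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("removing no components is the identity; removing all zeroes the EEG", {
  cfg <- strong_artifact_config(seed = 3)
  sess <- simulate_session(cfg)
  rec <- simulate_recording(sess$truth, cfg)
  model <- fit_ica(rec, seed = 2)

  same <- remove_components(rec, model, integer(0))
  expect_lt(max(abs(same$data - rec$data)), 1e-8)

  gone <- remove_components(rec, model, 1:12)
  eeg <- gone$data[gone$channels$role == "EEG", ]
  # only the channel means remain
  expect_lt(max(abs(sweep(eeg, 1, rowMeans(rec$data[rec$channels$role == "EEG", ])))), 1e-8)
  # EOG untouched
  expect_identical(
    gone$data[gone$channels$role == "EOG", ],
    rec$data[rec$channels$role == "EOG", ]
  )
  expect_error(remove_components(rec, model, 13), "1..12")
})

test_that("ICA cleaning removes the saccade artifact but keeps the FRP", {
  cfg <- strong_artifact_config(seed = 11)
  sess <- simulate_session(cfg)
  rec <- simulate_recording(sess$truth, cfg)
  model <- fit_ica(rec, seed = 2)
  sel <- select_artifact_components(model, rec)
  clean <- remove_components(rec, model, sel)

  onsets <- round(sess$truth$onset_ms[-1] / 1000 * cfg$fs_eeg) + 1
  win <- as.vector(outer(-12:0, onsets, "+"))
  win <- win[win > 0 & win <= ncol(rec$data)]
  sac_power <- function(r) mean(r$data["Fz", win]^2)
  expect_lt(sac_power(clean), 0.2 * sac_power(rec)) # >= 80 % reduction

  fx <- label_fixations(
    detect_fixations(sess$gaze, px_per_deg = 40), sess$layout
  )
  pk <- round(0.4 * cfg$fs_eeg)
  amp <- function(r) {
    ep <- extract_epochs(r, fx)
    tg <- ep$info$label == "target"
    mean(ep$data[tg, match("Pz", ep$channels$name), pk])
  }
  expect_lt(abs(amp(clean) - amp(rec)) / abs(amp(rec)), 0.10)
})

test_that("an 800 ms epoch at 256 Hz has exactly 205 samples and keeps labels", {
  ep <- ref_epochs()
  expect_equal(dim(ep$data)[3], 205L)
  expect_equal(round(0.8 * 256), 205)
  expect_setequal(unique(ep$info$label), c("target", "nontarget", "background"))
  subj <- ref_subject()
  expect_equal(nrow(ep$info), nrow(subj$truth))
})

test_that("fixations whose window exceeds the recording are dropped with a warning", {
  rec <- new_recording(matrix(rnorm(16 * 512), 16), fs = 256)
  fx <- tibble::tibble(
    onset_ms = c(100, 1990), duration_ms = 100,
    cx_px = 0, cy_px = 0, n_samples = 10L,
    label = c("target", "nontarget")
  )
  expect_warning(ep <- extract_epochs(rec, fx), "dropping 1")
  expect_equal(nrow(ep$info), 1)
  expect_equal(ep$info$label, "target")
})

test_that("epochs of a constant recording are constant", {
  rec <- new_recording(matrix(7, 16, 1024), fs = 256)
  fx <- tibble::tibble(
    onset_ms = 100, duration_ms = 100, cx_px = 0, cy_px = 0,
    n_samples = 10L, label = "target"
  )
  ep <- extract_epochs(rec, fx)
  expect_true(all(ep$data == 7))
})

test_that("band-pass keeps 5 Hz, kills 50 Hz and DC, and is linear", {
  fs <- 256
  t <- (0:204) / fs
  mid <- 52:154 # central half, clear of filter edge effects
  run <- function(x) bandpass_epochs(make_epochs(x))$data[1, 1, ]

  s5 <- sin(2 * pi * 5 * t)
  ratio5 <- sqrt(mean(run(s5)[mid]^2)) / sqrt(mean(s5[mid]^2))
  expect_lt(abs(ratio5 - 1), 0.05)

  s50 <- sin(2 * pi * 50 * t)
  ratio50 <- sqrt(mean(run(s50)[mid]^2)) / sqrt(mean(s50[mid]^2))
  expect_lt(ratio50, 0.10)

  dc <- run(rep(3, 205))
  expect_lt(max(abs(dc)) / 3, 0.01)

  set.seed(2)
  a <- rnorm(205)
  b <- rnorm(205)
  expect_lt(max(abs(run(2 * a + 3 * b) - 2 * run(a) - 3 * run(b))), 1e-8)

  expect_error(bandpass_epochs(make_epochs(a), lo = 10, hi = 5), "cutoffs")
  expect_error(bandpass_epochs(make_epochs(a), lo = 0.5, hi = 200), "cutoffs")
})

test_that("long windows get a true zero-phase high-pass", {
  fs <- 256
  t <- (0:1023) / fs
  mid <- 256:768
  run <- function(x) bandpass_epochs(make_epochs(x))$data[1, 1, ]
  s5 <- sin(2 * pi * 5 * t)
  expect_lt(abs(sqrt(mean(run(s5)[mid]^2)) / sqrt(mean(s5[mid]^2)) - 1), 0.05)
  expect_lt(max(abs(run(rep(3, 1024))[mid])) / 3, 0.01)
  # 0.1 Hz drift is below the 0.5 Hz cutoff and must be attenuated
  drift <- sin(2 * pi * 0.1 * t)
  expect_lt(sqrt(mean(run(drift)[mid]^2)) / sqrt(mean(drift[mid]^2)), 0.5)
})
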
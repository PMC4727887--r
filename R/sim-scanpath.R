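#' Simulate a single-trial scanpath over an object layout
#'
#' Emulates a visual-search trial through a gaze-contingent keyhole: the
#' simulated observer fixates non-target objects in a random order (with
#' occasional background fixations in between) until reaching the target, then
#' dwells on it. Fixation durations are drawn per class from a normal
#' distribution truncated below at `duration_floor_ms`; within-fixation samples
#' jitter around the centroid with SD `gaze_jitter_deg`, far below the
#' detection dispersion; saccades are constant-velocity sample runs of
#' `saccade_duration_ms` between centroids.
#'
#' A fixation's nominal duration is the drawn value; its realised sample count
#' is `round(duration * fs_gaze / 1000)`, so detected durations can differ from
#' the ground truth by up to one gaze-sample period.
#'
#' @param layout An [generate_layout()] object.
#' @param config An [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param t0_ms Start time of the first saccade-free sample, ms.
#' @return A list with `gaze` (tibble: `t_ms`, `x_px`, `y_px`, `valid`, with
#'   attribute `fs_gaze`) and `truth` (tibble: `onset_ms`, `duration_ms`,
#'   `cx_px`, `cy_px`, `label`).
#' @export
simulate_scanpath <- function(layout, config, seed = config$seed, t0_ms = 0) {
  stopifnot(inherits(layout, "frp_layout"), inherits(config, "frp_sim_config"))
  set.seed(seed)
  plan <- plan_trial_fixations(layout, config)
  build_gaze(plan, config, t0_ms)
}

# decide the sequence of (class, location) for one search trial; consecutive
# fixation centroids are kept far enough apart that intervening saccade
# samples never fall inside the detection dispersion circle of either fixation
plan_trial_fixations <- function(layout, config) {
  centers <- layout$centers
  tgt <- layout$target_index
  order <- sample(setdiff(1:12, tgt))
  n_visits <- sample.int(11, 1) # objects checked before the target is reached

  rows <- list()
  for (ob in order[seq_len(n_visits)]) {
    if (runif(1) < config$p_background) {
      bg <- sample_background_point(layout, config)
      rows[[length(rows) + 1]] <- list(cx = bg[1], cy = bg[2], label = "background")
    }
    rows[[length(rows) + 1]] <- list(
      cx = centers$cx_px[ob], cy = centers$cy_px[ob], label = "nontarget"
    )
  }
  # dwell on the found target; re-fixations land on opposite sides of the
  # object so each dwell is a separate, detectable fixation
  u <- runif(1, 0, 2 * pi)
  m <- layout$object_radius_deg * layout$px_per_deg - 10
  for (j in seq_len(config$n_target_dwell)) {
    rows[[length(rows) + 1]] <- list(
      cx = centers$cx_px[tgt] + cos(u) * m * (-1)^j,
      cy = centers$cy_px[tgt] + sin(u) * m * (-1)^j,
      label = "target"
    )
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

sample_background_point <- function(layout, config) {
  clearance_px <- (layout$object_radius_deg + 2) * layout$px_per_deg
  w <- config$screen_px[1]
  h <- config$screen_px[2]
  for (i in 1:500) {
    p <- c(runif(1, 0.05 * w, 0.95 * w), runif(1, 0.05 * h, 0.95 * h))
    d <- sqrt((layout$centers$cx_px - p[1])^2 + (layout$centers$cy_px - p[2])^2)
    if (min(d) > clearance_px) {
      return(p)
    }
  }
  abort("could not place a background fixation away from all objects")
}

# turn a planned fixation sequence into gaze samples + ground truth
build_gaze <- function(plan, config, t0_ms) {
  period <- 1000 / config$fs_gaze
  jit_px <- config$gaze_jitter_deg * config$px_per_deg
  n_sac <- max(1L, round(config$saccade_duration_ms / period))

  classes <- c("target", "nontarget", "background")
  dur <- numeric(nrow(plan))
  for (cl in classes) {
    idx <- which(plan$label == cl)
    dur[idx] <- rtruncnorm_lower(
      length(idx),
      config$fix_duration_means_ms[[cl]],
      config$fix_duration_sds_ms[[cl]],
      config$duration_floor_ms
    )
  }

  xs <- list()
  ys <- list()
  onsets <- numeric(nrow(plan))
  t_cursor <- t0_ms
  for (i in seq_len(nrow(plan))) {
    if (i > 1) { # ballistic saccade; samples sit in the middle half of the
      # flight path, clear of both fixations' dispersion circles
      frac <- seq(0.25, 0.75, length.out = n_sac)
      xs[[length(xs) + 1]] <- plan$cx[i - 1] + frac * (plan$cx[i] - plan$cx[i - 1])
      ys[[length(ys) + 1]] <- plan$cy[i - 1] + frac * (plan$cy[i] - plan$cy[i - 1])
      t_cursor <- t_cursor + n_sac * period
    }
    n_fix <- max(2L, round(dur[i] / period))
    onsets[i] <- t_cursor
    xs[[length(xs) + 1]] <- plan$cx[i] + rnorm(n_fix, 0, jit_px)
    ys[[length(ys) + 1]] <- plan$cy[i] + rnorm(n_fix, 0, jit_px)
    t_cursor <- t_cursor + n_fix * period
  }

  x <- unlist(xs)
  n <- length(x)
  gaze <- tibble::tibble(
    t_ms = t0_ms + (seq_len(n) - 1) * period,
    x_px = x,
    y_px = unlist(ys),
    valid = TRUE
  )
  attr(gaze, "fs_gaze") <- config$fs_gaze

  truth <- tibble::tibble(
    onset_ms = onsets,
    duration_ms = dur,
    cx_px = plan$cx,
    cy_px = plan$cy,
    label = plan$label
  )
  list(gaze = gaze, truth = truth)
}

#' Simulate a full session (all trials) for one subject
#'
#' Concatenates `config$n_trials` independent search trials, each over its own
#' jittered layout target but a common object grid, separated by
#' `trial_gap_ms`. A single layout is used for the whole session so that every
#' fixation can be labelled against one object map.
#'
#' @inheritParams simulate_scanpath
#' @return A list with `layout`, `gaze`, and `truth` (with a `trial` column).
#' @export
simulate_session <- function(config, seed = config$seed) {
  layout <- generate_layout(config, seed = seed)
  gaze_parts <- list()
  truth_parts <- list()
  t0 <- 0
  for (tr in seq_len(config$n_trials)) {
    sp <- simulate_scanpath(layout, config, seed = seed + 7919L * tr, t0_ms = t0)
    sp$truth$trial <- tr
    gaze_parts[[tr]] <- sp$gaze
    truth_parts[[tr]] <- sp$truth
    t0 <- max(sp$gaze$t_ms) + config$trial_gap_ms
  }
  gaze <- dplyr::bind_rows(gaze_parts)
  attr(gaze, "fs_gaze") <- config$fs_gaze
  list(layout = layout, gaze = gaze, truth = dplyr::bind_rows(truth_parts))
}
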
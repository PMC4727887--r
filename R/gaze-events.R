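#' Detect fixations with a dispersion/duration threshold
#'
#' Identification by dispersion threshold (I-DT) in the style of remote
#' eye-tracker vendor algorithms: consecutive valid samples belong to one
#' fixation while they all fall inside a circle with a diameter of
#' `dispersion_deg` degrees of visual angle, anchored at the running centroid
#' of the samples accrued so far. Runs spanning at least `min_duration_ms`
#' (default 60 ms, the vendor-recommended temporal threshold) become
#' fixations; shorter runs are discarded. A fixation's duration is
#' `n_samples / fs_gaze * 1000` ms and its centroid is the mean of its member
#' samples. Up to one consecutive invalid sample inside a run is tolerated
#' (skipped, not included); longer invalid gaps break the run.
#'
#' @param gaze Tibble with columns `t_ms`, `x_px`, `y_px`, `valid` (an
#'   `fs_gaze` attribute is used when present, otherwise the rate is inferred
#'   from the median sample interval).
#' @param dispersion_deg Dispersion threshold, interpreted as a circle
#'   *diameter* in degrees.
#' @param min_duration_ms Temporal threshold, ms.
#' @param px_per_deg Pixels per degree of visual angle.
#' @return A tibble of fixations: `onset_ms`, `duration_ms`, `cx_px`, `cy_px`,
#'   `n_samples`, `label` (initialised to `"unlabelled"`), ordered by onset and
#'   pairwise non-overlapping in time.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   t_ms = seq(0, by = 1000 / 120, length.out = 12),
#'   x_px = 500, y_px = 400, valid = TRUE
#' )
#' detect_fixations(g, px_per_deg = 40)
detect_fixations <- function(gaze, dispersion_deg = 2, min_duration_ms = 60,
                             px_per_deg) {
  stopifnot(px_per_deg > 0, dispersion_deg > 0)
  empty <- tibble::tibble(
    onset_ms = numeric(), duration_ms = numeric(), cx_px = numeric(),
    cy_px = numeric(), n_samples = integer(), label = character()
  )
  if (is.null(gaze) || nrow(gaze) == 0 || sum(gaze$valid) < 2) {
    return(empty)
  }
  fs <- attr(gaze, "fs_gaze") %||% (1000 / stats::median(diff(gaze$t_ms)))
  radius_px <- dispersion_deg / 2 * px_per_deg

  out <- list()
  run <- integer(0) # indices of current run members
  cx <- cy <- 0
  gap <- 0L
  finalize <- function(run) {
    n <- length(run)
    if (n >= 2 && n / fs * 1000 >= min_duration_ms) {
      tibble::tibble(
        onset_ms = gaze$t_ms[run[1]],
        duration_ms = n / fs * 1000,
        cx_px = mean(gaze$x_px[run]),
        cy_px = mean(gaze$y_px[run]),
        n_samples = n,
        label = "unlabelled"
      )
    } else {
      NULL
    }
  }
  for (i in seq_len(nrow(gaze))) {
    if (!gaze$valid[i]) {
      gap <- gap + 1L
      if (gap > 1L) { # long dropout: break the run
        out[[length(out) + 1]] <- finalize(run)
        run <- integer(0)
        gap <- 0L
      }
      next
    }
    gap <- 0L
    if (length(run) == 0) {
      run <- i
      cx <- gaze$x_px[i]
      cy <- gaze$y_px[i]
    } else if (sqrt((gaze$x_px[i] - cx)^2 + (gaze$y_px[i] - cy)^2) <= radius_px) {
      run <- c(run, i)
      cx <- cx + (gaze$x_px[i] - cx) / length(run) # running centroid
      cy <- cy + (gaze$y_px[i] - cy) / length(run)
    } else {
      out[[length(out) + 1]] <- finalize(run)
      run <- i
      cx <- gaze$x_px[i]
      cy <- gaze$y_px[i]
    }
  }
  out[[length(out) + 1]] <- finalize(run)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Label fixations by their location on the object layout
#'
#' A fixation is an onto-object fixation when its centroid falls inside a
#' circular area of `onto_object_radius_deg` degrees of visual angle
#' (by default 2.5 deg, about 100 px at 40 px/deg) anchored at an object
#' center: the target object's area gives the label `target`, any other
#' object's `nontarget`, everything else `background`. If a centroid lies
#' inside two areas the nearest center wins.
#'
#' @param fixations Fixation tibble from [detect_fixations()].
#' @param layout An `frp_layout`.
#' @param onto_object_radius_deg Labelling radius, degrees.
#' @param px_per_deg Pixels per degree (defaults to the layout's).
#' @return The fixation tibble with `label` filled in.
#' @export
label_fixations <- function(fixations, layout,
                            onto_object_radius_deg = 2.5,
                            px_per_deg = layout$px_per_deg) {
  stopifnot(inherits(layout, "frp_layout"), nrow(layout$centers) == 12)
  if (nrow(fixations) == 0) {
    return(fixations)
  }
  radius_px <- onto_object_radius_deg * px_per_deg
  d <- outer(fixations$cx_px, layout$centers$cx_px, "-")^2 +
    outer(fixations$cy_px, layout$centers$cy_px, "-")^2
  nearest <- max.col(-d, ties.method = "first")
  inside <- sqrt(d[cbind(seq_len(nrow(d)), nearest)]) <= radius_px
  fixations$label <- dplyr::case_when(
    inside & nearest == layout$target_index ~ "target",
    inside ~ "nontarget",
    .default = "background"
  )
  fixations
}
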
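#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one
#' serialisable object. All defaults can be overridden; the configuration
#' round-trips losslessly through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param sim An [sim_config()] for synthetic input (ignored when `data_dir`
#'   points at stored recordings).
#' @param data_dir Optional directory with stored per-subject artifacts
#'   (`gaze_<s>.tsv`, `recording_<s>.tsv`, `layout_<s>.tsv`); `NULL` simulates.
#' @param dispersion_deg,min_duration_ms Fixation-detection thresholds.
#' @param onto_object_radius_deg Onto-object labelling radius, degrees.
#' @param use_ica Run ICA ocular-artifact removal.
#' @param corr_threshold EOG-correlation threshold for artifact components.
#' @param bandpass Numeric `c(lo, hi)`, Hz.
#' @param epoch_ms Epoch length, ms.
#' @param channel_set `"EEG"`, `"EOG"` or `"ALL"`.
#' @param contrast Class contrast (see [run_intra_subject()]).
#' @param scheme `"intra"` or `"inter"`.
#' @param k Folds for the intra-subject scheme.
#' @param pca_criterion Explained-variance criterion.
#' @param lambda Shrinkage intensity (`NULL` = analytic estimate).
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `frp_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            data_dir = NULL,
                            dispersion_deg = 2,
                            min_duration_ms = 60,
                            onto_object_radius_deg = 2.5,
                            use_ica = TRUE,
                            corr_threshold = 0.7,
                            bandpass = c(0.5, 10),
                            epoch_ms = 800,
                            channel_set = "EEG",
                            contrast = "target_vs_rest",
                            scheme = c("intra", "inter"),
                            k = 10,
                            pca_criterion = 0.999,
                            lambda = NULL,
                            seed = 1L) {
  cfg <- list(
    sim = sim, data_dir = data_dir,
    dispersion_deg = dispersion_deg, min_duration_ms = min_duration_ms,
    onto_object_radius_deg = onto_object_radius_deg,
    use_ica = use_ica, corr_threshold = corr_threshold,
    bandpass = bandpass, epoch_ms = epoch_ms,
    channel_set = channel_set, contrast = contrast,
    scheme = match.arg(scheme), k = k,
    pca_criterion = pca_criterion, lambda = lambda,
    seed = as.integer(seed)
  )
  class(cfg) <- "frp_pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config An `frp_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  sim <- unclass(lst$sim)
  for (nm in c(
    "fix_duration_means_ms", "fix_duration_sds_ms",
    "frp_amplitude_uv", "topography", "eog_artifact_gain"
  )) {
    sim[[nm]] <- as.list(sim[[nm]]) # keep names: yaml drops them on plain vectors
  }
  lst$sim <- sim
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lst <- yaml::read_yaml(path)
  sim <- lst$sim
  for (nm in c(
    "fix_duration_means_ms", "fix_duration_sds_ms",
    "frp_amplitude_uv", "topography", "eog_artifact_gain"
  )) {
    sim[[nm]] <- unlist(sim[[nm]])
  }
  sim$screen_px <- unlist(sim$screen_px)
  lst$sim <- do.call(sim_config, sim)
  lst$bandpass <- unlist(lst$bandpass)
  do.call(pipeline_config, lst)
}

# preprocess one subject: detect -> label -> (ICA) -> epochs -> bandpass
preprocess_subject <- function(subj, config) {
  fx <- detect_fixations(subj$gaze,
    dispersion_deg = config$dispersion_deg,
    min_duration_ms = config$min_duration_ms,
    px_per_deg = subj$layout$px_per_deg
  )
  fx <- label_fixations(fx, subj$layout,
    onto_object_radius_deg = config$onto_object_radius_deg
  )
  rec <- subj$recording
  ica <- NULL
  removed <- integer(0)
  if (isTRUE(config$use_ica)) {
    ica <- fit_ica(rec, seed = config$seed + 17L)
    removed <- select_artifact_components(ica, rec,
      corr_threshold = config$corr_threshold
    )
    rec <- remove_components(rec, ica, removed)
  }
  ep <- extract_epochs(rec, fx,
    epoch_ms = config$epoch_ms,
    subject_id = subj$subject_id
  )
  ep <- bandpass_epochs(ep, lo = config$bandpass[1], hi = config$bandpass[2])
  list(fixations = fx, epochs = ep, ica = ica, removed = removed)
}

load_subject <- function(data_dir, s) {
  paths <- file.path(data_dir, sprintf(
    c("gaze_%d.tsv", "recording_%d.tsv", "layout_%d.tsv"), s
  ))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  lay_df <- readr::read_tsv(paths[3], comment = "#", show_col_types = FALSE)
  meta <- read_meta(paths[3])
  layout <- structure(
    list(
      centers = lay_df,
      target_index = as.integer(meta$target_index),
      object_radius_deg = as.numeric(meta$object_radius_deg),
      px_per_deg = as.numeric(meta$px_per_deg)
    ),
    class = "frp_layout"
  )
  list(
    subject_id = s, gaze = read_gaze(paths[1]),
    recording = read_recording(paths[2]), layout = layout
  )
}

#' Write a simulated subject's artifacts to a directory
#'
#' @param subj One element of [simulate_dataset()] output.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_subject <- function(subj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- subj$subject_id
  write_gaze(subj$gaze, file.path(dir, sprintf("gaze_%d.tsv", s)))
  write_recording(subj$recording, file.path(dir, sprintf("recording_%d.tsv", s)))
  write_meta_tsv(
    subj$layout$centers,
    file.path(dir, sprintf("layout_%d.tsv", s)),
    list(
      target_index = subj$layout$target_index,
      object_radius_deg = subj$layout$object_radius_deg,
      px_per_deg = subj$layout$px_per_deg
    )
  )
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) co-registered gaze + EEG data, detect and label
#' fixations, remove ocular artifacts, extract and filter fixation-locked
#' epochs, and evaluate the configured class contrast and channel set under
#' the configured cross-validation scheme. Identical configuration and seed
#' give identical outputs.
#'
#' @param config An [pipeline_config()] object.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `frp_pipeline_result`: `results` (per-fold or
#'   per-subject metric tibble), `summary` (named list with `mean_metric`,
#'   `sd_metric`, counts), `fixations`, `epochs`, `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "frp_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- config$sim
  sim$seed <- config$seed
  subjects <- stage("input", {
    if (is.null(config$data_dir)) {
      say("simulating %d subject(s), seed %d", sim$n_subjects, sim$seed)
      simulate_dataset(sim)
    } else {
      s <- 1L
      out <- list()
      while (file.exists(file.path(config$data_dir, sprintf("gaze_%d.tsv", s)))) {
        out[[s]] <- load_subject(config$data_dir, s)
        s <- s + 1L
      }
      if (!length(out)) {
        abort(paste0("no subject files found in ", config$data_dir))
      }
      out
    }
  })

  prep <- stage("preprocess", purrr::map(subjects, function(su) {
    say(
      "subject %d: detecting fixations and preprocessing (ICA: %s)",
      su$subject_id, config$use_ica
    )
    preprocess_subject(su, config)
  }))
  epochs_list <- purrr::map(prep, "epochs")
  fixations <- dplyr::bind_rows(
    purrr::imap(prep, ~ dplyr::mutate(.x$fixations, subject_id = .y))
  )

  results <- stage("evaluate", {
    if (config$scheme == "intra") {
      dplyr::bind_rows(purrr::imap(epochs_list, function(ep, s) {
        dplyr::mutate(
          run_intra_subject(ep,
            contrast = config$contrast,
            channel_set = config$channel_set,
            seed = config$seed + 101L * s, k = config$k,
            pca_criterion = config$pca_criterion, lambda = config$lambda
          ),
          subject_id = s
        )
      }))
    } else {
      dplyr::mutate(
        run_inter_subject(epochs_list,
          contrast = config$contrast,
          channel_set = config$channel_set, seed = config$seed,
          pca_criterion = config$pca_criterion, lambda = config$lambda
        ),
        subject_id = .data$fold
      )
    }
  })

  structure(
    list(
      results = results,
      summary = list(
        scheme = config$scheme, contrast = config$contrast,
        channel_set = toupper(config$channel_set),
        metric = results$metric[1],
        mean_metric = mean(results$value),
        sd_metric = sd(results$value),
        n_subjects = length(subjects),
        n_epochs = sum(purrr::map_int(epochs_list, ~ nrow(.x$info))),
        n_fixations = nrow(fixations),
        components_removed = purrr::map(prep, "removed")
      ),
      fixations = fixations,
      epochs = epochs_list,
      config = config
    ),
    class = "frp_pipeline_result"
  )
}

#' @export
print.frp_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<frp_pipeline_result> %s / %s / %s: mean %s = %.3f (sd %.3f), %d subject(s), %d epochs\n",
    s$scheme, s$contrast, s$channel_set, s$metric,
    s$mean_metric, s$sd_metric, s$n_subjects, s$n_epochs
  ))
  invisible(x)
}
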
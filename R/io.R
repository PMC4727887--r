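#' Read and write pipeline artifacts as tab-separated text
#'
#' All on-disk artifacts are plain TSV with `#key: value` comment headers for
#' metadata (sampling rates, channel roles), so every stage can be inspected
#' with standard command-line tools.
#'
#' @param gaze,fixations,recording,epochs Objects produced by the respective
#'   stages.
#' @param path File path.
#' @name frp_io
NULL

write_meta_tsv <- function(df, path, meta = list()) {
  lines <- vapply(names(meta), function(k) {
    sprintf("#%s: %s", k, paste(meta[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
}

read_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    kv <- sub("^#", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- strsplit(trimws(sub("^[^:]*:", "", kv)), ",")[[1]]
  }
  meta
}

#' @rdname frp_io
#' @export
write_gaze <- function(gaze, path) {
  write_meta_tsv(gaze, path, list(fs_gaze = attr(gaze, "fs_gaze")))
  invisible(path)
}

#' @rdname frp_io
#' @export
read_gaze <- function(path) {
  meta <- read_meta(path)
  g <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  g$valid <- as.logical(g$valid)
  if (!is.null(meta$fs_gaze)) attr(g, "fs_gaze") <- as.numeric(meta$fs_gaze)
  g
}

#' @rdname frp_io
#' @export
write_fixations <- function(fixations, path) {
  write_meta_tsv(fixations, path)
  invisible(path)
}

#' @rdname frp_io
#' @export
read_fixations <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' @rdname frp_io
#' @export
write_recording <- function(recording, path) {
  df <- tibble::as_tibble(t(recording$data), .name_repair = "minimal")
  names(df) <- recording$channels$name
  write_meta_tsv(df, path, list(
    fs = recording$fs,
    roles = recording$channels$role
  ))
  invisible(path)
}

#' @rdname frp_io
#' @export
read_recording <- function(path) {
  meta <- read_meta(path)
  df <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  new_recording(
    t(as.matrix(df)),
    fs = as.numeric(meta$fs),
    channels = tibble::tibble(name = names(df), role = meta$roles)
  )
}

#' @rdname frp_io
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  df <- tibble::as_tibble(flat, .name_repair = ~ paste0("s", seq_len(d[3])))
  df <- dplyr::bind_cols(
    tibble::tibble(
      epoch = rep(seq_len(d[1]), each = d[2]),
      channel = rep(epochs$channels$name, d[1]),
      label = rep(epochs$info$label, each = d[2]),
      subject_id = rep(epochs$info$subject_id, each = d[2]),
      onset_sample = rep(epochs$info$onset_sample, each = d[2])
    ),
    df
  )
  write_meta_tsv(df, path, list(fs = epochs$fs, roles = epochs$channels$role))
  invisible(path)
}

#' @rdname frp_io
#' @export
read_epochs <- function(path) {
  meta <- read_meta(path)
  df <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  chans <- unique(df$channel)
  n_ep <- max(df$epoch)
  len <- sum(grepl("^s[0-9]+$", names(df)))
  vals <- as.matrix(df[, paste0("s", seq_len(len))])
  data <- array(0, dim = c(n_ep, length(chans), len))
  for (i in seq_len(nrow(df))) {
    data[df$epoch[i], match(df$channel[i], chans), ] <- vals[i, ]
  }
  first <- !duplicated(df$epoch)
  structure(
    list(
      data = data,
      info = tibble::tibble(
        epoch = df$epoch[first],
        onset_sample = df$onset_sample[first],
        label = df$label[first],
        subject_id = df$subject_id[first]
      ),
      fs = as.numeric(meta$fs),
      channels = tibble::tibble(name = chans, role = meta$roles)
    ),
    class = "frp_epochs"
  )
}
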
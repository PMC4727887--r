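#' ROC curve and AUC from a fixed threshold sweep
#'
#' Classifier outputs are min-max mapped onto `[0, 1]` and swept with `K`
#' equally spaced thresholds `b_1 = 0, ..., b_K = 1`; at each threshold the
#' true-positive rate is expressed as a function of the false-positive rate,
#' and the AUC is the trapezoidal area under the resulting curve. The min-max
#' mapping is monotone, so the AUC equals (up to the K-threshold
#' discretisation) the rank-based AUC of the raw scores. Chance level is
#' always 0.5 regardless of class priors.
#'
#' @param scores Real-valued classifier outputs (higher = more positive).
#' @param labels Class label per score.
#' @param positive The label counted as positive.
#' @param K Number of thresholds.
#' @return An object of class `frp_roc`: `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `K`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "target", K = 100) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)), K >= 2)
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute a ROC curve")
  }
  rng <- range(scores)
  s <- if (diff(rng) == 0) rep(0.5, length(scores)) else (scores - rng[1]) / diff(rng)
  th <- seq(0, 1, length.out = K)
  tpr <- vapply(th, function(b) sum(s[is_pos] >= b) / n_pos, numeric(1))
  fpr <- vapply(th, function(b) sum(s[!is_pos] >= b) / n_neg, numeric(1))
  # close the curve at (0, 0); the sweep itself starts at (1, 1) for b = 0
  xs <- c(fpr, 0)
  ys <- c(tpr, 0)
  ord <- order(xs, ys)
  xs <- xs[ord]
  ys <- ys[ord]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  structure(
    list(
      curve = tibble::tibble(threshold = th, fpr = fpr, tpr = tpr),
      auc = auc, K = K, n_pos = n_pos, n_neg = n_neg
    ),
    class = "frp_roc"
  )
}

#' @export
print.frp_roc <- function(x, ...) {
  cat(sprintf(
    "<frp_roc> AUC = %.4f (%d thresholds, %d positive / %d negative)\n",
    x$auc, x$K, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Stratified k-fold split
#'
#' Disjoint covering folds in which every class appears in the same proportion
#' as in the full set (per-fold class counts differ from the exact proportion
#' by at most one sample).
#'
#' @param labels Class label per observation; every class must have >= k
#'   members.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer vectors (test indices per fold).
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf(
      "every class needs >= k = %d samples (smallest has %d)",
      k, min(counts)
    ))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(sample(k), length.out = length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Down-sample to balanced class counts
#'
#' Randomly (seeded) down-samples every class to the size of the smallest one.
#'
#' @param labels Class label per observation.
#' @param seed Integer seed.
#' @return Sorted integer vector of retained indices.
#' @export
balance_classes <- function(labels, seed = 1) {
  labels <- as.character(labels)
  m <- min(table(labels))
  set.seed(seed)
  keep <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == m) idx else sample(idx, m)
  }))
  sort(keep)
}

#' Two-tailed paired t-test
#'
#' Thin wrapper around [stats::t.test()] returning a tidy row. Degenerate
#' zero-variance differences are handled explicitly: identical samples give
#' `t = 0, p = 1`; a constant non-zero difference gives `t = +/-Inf, p = 0`.
#'
#' @param a,b Paired metric vectors of equal length (n >= 2).
#' @return Tibble with `statistic`, `p_value`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  if (length(a) < 2) abort("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(
        statistic = 0, p_value = 1, df = length(d) - 1, mean_diff = 0
      ))
    }
    return(tibble::tibble(
      statistic = sign(mean(d)) * Inf, p_value = 0,
      df = length(d) - 1, mean_diff = mean(d)
    ))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter), mean_diff = unname(tt$estimate)
  )
}

# map epoch labels to a class contrast; returns indices, labels, positive class
contrast_labels <- function(labels, contrast) {
  contrast <- match.arg(contrast, c(
    "target_vs_rest", "target_vs_nontarget", "target_vs_background",
    "nontarget_vs_background", "three_class"
  ))
  labels <- as.character(labels)
  switch(contrast,
    target_vs_rest = list(
      idx = seq_along(labels),
      labels = ifelse(labels == "target", "target", "rest"),
      positive = "target"
    ),
    target_vs_nontarget = {
      idx <- which(labels %in% c("target", "nontarget"))
      list(idx = idx, labels = labels[idx], positive = "target")
    },
    target_vs_background = {
      idx <- which(labels %in% c("target", "background"))
      list(idx = idx, labels = labels[idx], positive = "target")
    },
    nontarget_vs_background = {
      idx <- which(labels %in% c("nontarget", "background"))
      list(idx = idx, labels = labels[idx], positive = "nontarget")
    },
    three_class = list(
      idx = seq_along(labels), labels = labels, positive = NA_character_
    )
  )
}

# fit PCA + FDA on the training rows and score the test rows
fit_and_score <- function(x, labels, train, test, positive,
                          pca_criterion = 0.999, lambda = NULL) {
  pca <- fit_pca(x[train, , drop = FALSE], criterion = pca_criterion)
  ztr <- predict(pca, x[train, , drop = FALSE])
  zte <- predict(pca, x[test, , drop = FALSE])
  model <- fit_fda(ztr, labels[train], lambda = lambda)
  if (is.na(positive)) { # multi-class: balanced accuracy
    pred <- classify(model, zte)
    list(metric = "accuracy", value = mean(pred == labels[test]))
  } else {
    s <- decision_scores(model, zte)
    if (model$class_labels[1] != positive) s <- -s
    list(metric = "auc", value = roc_auc(s, labels[test], positive)$auc)
  }
}

#' Intra-subject stratified 10-fold cross-validation
#'
#' One subject's epochs are split into `k` stratified folds; for every fold the
#' PCA projection, the shrinkage intensity and the FDA classifier are fitted on
#' the remaining folds only and evaluated on the held-out fold. Binary
#' contrasts keep the true class priors and report the AUC; the three-class
#' contrast balances the classes first (seeded down-sampling) and reports
#' accuracy.
#'
#' @param epochs An `frp_epochs` object (one subject).
#' @param contrast One of `"target_vs_rest"`, `"target_vs_nontarget"`,
#'   `"target_vs_background"`, `"nontarget_vs_background"`, `"three_class"`.
#' @param channel_set `"EEG"`, `"EOG"` or `"ALL"`.
#' @param seed Integer seed for fold assignment (and balancing).
#' @param k Number of folds.
#' @param pca_criterion Explained-variance criterion for [fit_pca()].
#' @param lambda Shrinkage intensity; `NULL` = analytic estimate per fold.
#' @param leak If `TRUE`, deliberately fit PCA and FDA on *all* data (training
#'   plus test) before scoring the test folds. Only useful as a negative
#'   control: on null data this inflates the apparent AUC and demonstrates why
#'   fold-wise fitting matters. Never use for reported results.
#' @return A `frp_cv` tibble: `scheme`, `contrast`, `channel_set`, `fold`,
#'   `metric`, `value`.
#' @export
run_intra_subject <- function(epochs, contrast = "target_vs_rest",
                              channel_set = "EEG", seed = 1, k = 10,
                              pca_criterion = 0.999, lambda = NULL,
                              leak = FALSE) {
  feats <- concatenate_epochs(epochs, channel_set)
  ct <- contrast_labels(feats$info$label, contrast)
  x <- feats$x[ct$idx, , drop = FALSE]
  labs <- ct$labels
  if (contrast == "three_class") {
    keep <- balance_classes(labs, seed = seed)
    x <- x[keep, , drop = FALSE]
    labs <- labs[keep]
  }
  folds <- stratified_kfold(labs, k = k, seed = seed)
  rows <- purrr::map(seq_along(folds), function(f) {
    test <- folds[[f]]
    train <- if (leak) seq_along(labs) else setdiff(seq_along(labs), test)
    res <- fit_and_score(x, labs, train, test, ct$positive,
      pca_criterion = pca_criterion, lambda = lambda
    )
    tibble::tibble(
      scheme = "intra_subject_10fold", contrast = contrast,
      channel_set = toupper(channel_set), fold = f,
      metric = res$metric, value = res$value
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("frp_cv", class(out))
  out
}

#' Inter-subject leave-one-subject-out evaluation
#'
#' For every subject the classifier (PCA + shrinkage FDA) is trained on the
#' pooled epochs of all *other* subjects and evaluated on the held-out
#' subject's epochs, so training data contain exclusively data from other
#' participants.
#'
#' @param epochs_list List of `frp_epochs`, one per subject (>= 2).
#' @inheritParams run_intra_subject
#' @return A `frp_cv` tibble with one row per held-out subject.
#' @export
run_inter_subject <- function(epochs_list, contrast = "target_vs_rest",
                              channel_set = "EEG", seed = 1,
                              pca_criterion = 0.999, lambda = NULL) {
  if (length(epochs_list) < 2) abort("inter-subject evaluation needs >= 2 subjects")
  feats <- purrr::map(epochs_list, concatenate_epochs, channel_set = channel_set)
  x <- do.call(rbind, purrr::map(feats, "x"))
  labels <- unlist(purrr::map(feats, ~ .x$info$label))
  subject <- rep(seq_along(feats), purrr::map_int(feats, ~ nrow(.x$x)))
  ct <- contrast_labels(labels, contrast)
  x <- x[ct$idx, , drop = FALSE]
  labs <- ct$labels
  subj <- subject[ct$idx]
  if (contrast == "three_class") {
    keep <- balance_classes(labs, seed = seed)
    x <- x[keep, , drop = FALSE]
    labs <- labs[keep]
    subj <- subj[keep]
  }
  rows <- purrr::map(sort(unique(subj)), function(s) {
    res <- fit_and_score(x, labs, which(subj != s), which(subj == s),
      ct$positive,
      pca_criterion = pca_criterion, lambda = lambda
    )
    tibble::tibble(
      scheme = "inter_subject_loso", contrast = contrast,
      channel_set = toupper(channel_set), fold = s,
      metric = res$metric, value = res$value
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("frp_cv", class(out))
  out
}

#' Export the 2-D discriminant projection of feature vectors
#'
#' Coordinates of every sample on the two leading axes of a fitted multi-class
#' discriminant, for inspecting linear separability.
#'
#' @param model A fitted `frp_fda` with >= 3 classes.
#' @param x Feature matrix (observations x d).
#' @param labels Class label per row.
#' @return Tibble with `ld1`, `ld2`, `label`.
#' @export
export_fda_projection <- function(model, x, labels) {
  stopifnot(inherits(model, "frp_fda"))
  if (ncol(model$P) < 2) {
    abort("2-D projection export requires a model with at least 3 classes")
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  proj <- x %*% model$P[, 1:2]
  tibble::tibble(ld1 = proj[, 1], ld2 = proj[, 2], label = as.character(labels))
}
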
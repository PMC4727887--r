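#' Between- and within-class scatter matrices
#'
#' For classes \eqn{C_j} with counts \eqn{N_{C_j}}, class means \eqn{\mu_{C_j}}
#' and the average of class means \eqn{\mu = \frac{1}{n_{cls}}\sum_j
#' \mu_{C_j}}:
#' \deqn{S_b = \sum_j N_{C_j} (\mu_{C_j}-\mu)(\mu_{C_j}-\mu)^T, \quad
#'       S_w = \sum_j \sum_{i \in C_j} (x_i-\mu_{C_j})(x_i-\mu_{C_j})^T.}
#' Note the global mean averages the class means rather than the pooled
#' samples, so the two differ under class imbalance.
#'
#' @param x Numeric matrix (observations x d).
#' @param labels Class label per row; at least 2 classes with >= 2 samples
#'   each.
#' @return List with `S_b`, `S_w`, `class_labels`, `class_counts`,
#'   `class_means` (d x n_classes), `mu`.
#' @export
scatter_matrices <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) < 2) abort("need at least 2 classes")
  counts <- table(factor(labels, levels = cls))
  if (any(counts < 2)) {
    abort(paste0(
      "every class needs >= 2 samples; offending: ",
      paste(cls[counts < 2], collapse = ", ")
    ))
  }
  d <- ncol(x)
  means <- vapply(cls, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
    numeric(d)
  )
  means <- matrix(means, nrow = d, dimnames = list(NULL, cls))
  mu <- rowMeans(means)
  s_b <- matrix(0, d, d)
  s_w <- matrix(0, d, d)
  for (cl in cls) {
    dm <- means[, cl] - mu
    s_b <- s_b + counts[[cl]] * tcrossprod(dm)
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, means[, cl])
    s_w <- s_w + crossprod(xc)
  }
  list(
    S_b = s_b, S_w = s_w, class_labels = cls,
    class_counts = as.integer(counts), class_means = means, mu = mu
  )
}

#' Shrink a covariance matrix towards the equal-variance diagonal target
#'
#' \deqn{\Sigma^* = \lambda \nu I + (1-\lambda) S, \qquad \nu =
#' \mathrm{tr}(S)/d,} the convex combination of the sample covariance with a
#' diagonal target in which all variances are equal and all covariances zero.
#' For any \eqn{\lambda > 0} the result is positive definite even when `S` is
#' rank-deficient (provided `S` is not identically zero).
#'
#' @param S Symmetric positive semi-definite matrix.
#' @param lambda Shrinkage intensity in `[0, 1]`.
#' @return The shrunk covariance matrix.
#' @export
shrink_covariance <- function(S, lambda) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (lambda < 0 || lambda > 1) abort("shrinkage intensity must lie in [0, 1]")
  nu <- mean(diag(S))
  lambda * nu * diag(nrow(S)) + (1 - lambda) * S
}

#' Analytic shrinkage intensity for the equal-variance diagonal target
#'
#' Plug-in estimate of the optimal shrinkage intensity: the ratio of the summed
#' sampling variances of the covariance entries to the summed squared distances
#' between the sample covariance and the target, clipped to `[0, 1]`. Computed
#' on class-centered data so the estimate refers to the pooled within-class
#' covariance.
#'
#' @inheritParams scatter_matrices
#' @return Shrinkage intensity in `[0, 1]`; degenerate data returns 1.
#' @export
estimate_shrinkage_intensity <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  n <- nrow(x)
  cc <- x
  for (cl in unique(labels)) {
    i <- labels == cl
    cc[i, ] <- sweep(x[i, , drop = FALSE], 2, colMeans(x[i, , drop = FALSE]))
  }
  s <- crossprod(cc) / (n - 1)
  nu <- mean(diag(s))
  target <- diag(nu, ncol(x))
  den <- sum((s - target)^2)
  if (den < .Machine$double.eps) {
    return(1)
  }
  # sum over entries of Var_k[(x_ki - mu_i)(x_kj - mu_j)], computed without
  # forming the d x d x n array
  sbar <- crossprod(cc) / n
  num <- (n / (n - 1)^2) * (sum(rowSums(cc^2)^2) / n - sum(sbar^2))
  min(1, max(0, num / den))
}

#' Fit a shrinkage-regularised Fisher discriminant
#'
#' Maximises \eqn{\mathrm{tr}\{(P^T \Sigma^* P)^{-1} P^T S_b P\}} where
#' \eqn{\Sigma^*} is the shrunk pooled within-class covariance, solved as the
#' generalized eigenvalue problem \eqn{S_b V = \lambda \Sigma^* V} via a
#' Cholesky reduction to a symmetric eigenproblem. The projection keeps the
#' `n_classes - 1` leading generalized eigenvectors (sign-fixed: largest
#' magnitude entry positive). For two classes the model additionally exposes
#' the weight vector \eqn{w \propto \Sigma^{*-1}(\mu_1 - \mu_2)} and bias
#' \eqn{b = -w\cdot(\mu_1+\mu_2)/2} (midpoint rule); decision scores are
#' \eqn{y = x \cdot w + b} with the sign giving the class.
#'
#' @inheritParams scatter_matrices
#' @param lambda Shrinkage intensity; `NULL` (default) uses the analytic
#'   estimate of [estimate_shrinkage_intensity()].
#' @return An object of class `frp_fda`.
#' @export
fit_fda <- function(x, labels, lambda = NULL) {
  if (inherits(x, "frp_features")) {
    labels <- labels %||% x$info$label
    x <- x$x
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  sc <- scatter_matrices(x, labels)
  n <- nrow(x)
  n_cls <- length(sc$class_labels)
  if (is.null(lambda)) lambda <- estimate_shrinkage_intensity(x, labels)
  cw <- sc$S_w / (n - n_cls) # pooled within-class covariance
  sigma_star <- shrink_covariance(cw, lambda)
  ch <- tryCatch(chol(sigma_star), error = function(e) NULL)
  if (is.null(ch)) {
    abort(paste(
      "shrunk within-class covariance is singular;",
      "enable shrinkage (lambda > 0) to regularise it"
    ))
  }
  li <- backsolve(ch, diag(ncol(x)))
  m <- crossprod(li, sc$S_b %*% li)
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  keep <- seq_len(n_cls - 1)
  p <- li %*% eg$vectors[, keep, drop = FALSE]
  flip <- apply(p, 2, function(col) sign(col[which.max(abs(col))]))
  p <- sweep(p, 2, flip, "*")

  w <- NULL
  b <- NULL
  if (n_cls == 2) {
    w <- solve(sigma_star, sc$class_means[, 1] - sc$class_means[, 2])
    b <- -sum(w * (sc$class_means[, 1] + sc$class_means[, 2]) / 2)
  }
  structure(
    list(
      P = p,
      eigenvalues = eg$values[keep],
      Sigma_star = sigma_star,
      S_b = sc$S_b, S_w = sc$S_w,
      lambda = lambda,
      class_labels = sc$class_labels,
      class_counts = sc$class_counts,
      class_means = sc$class_means,
      mu = sc$mu,
      means_projected = crossprod(p, sc$class_means),
      w = w, b = b,
      n = n, d = ncol(x)
    ),
    class = "frp_fda"
  )
}

#' @export
print.frp_fda <- function(x, ...) {
  cat(sprintf(
    "<frp_fda> %d classes (%s), d = %d, n = %d, shrinkage lambda = %.4f\n",
    length(x$class_labels), paste(x$class_labels, collapse = "/"),
    x$d, x$n, x$lambda
  ))
  invisible(x)
}

#' Binary decision scores
#'
#' Scalar products `y = x . w + b`; positive scores vote for the first class
#' label, negative for the second.
#'
#' @param model A fitted binary `frp_fda`.
#' @param x Matrix (observations x d) or length-d vector.
#' @return Numeric vector of scores.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "frp_fda"))
  if (is.null(model$w)) {
    abort("decision scores are defined for binary models only")
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  drop(x %*% model$w + model$b)
}

#' Classify observations with a fitted discriminant
#'
#' Binary models use the sign of the decision score; multi-class models assign
#' the nearest projected class mean (Euclidean distance in the discriminant
#' space).
#'
#' @param model A fitted `frp_fda`.
#' @param x Matrix (observations x d) or length-d vector.
#' @return Character vector of predicted class labels.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "frp_fda"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.null(model$w)) {
    s <- decision_scores(model, x)
    return(ifelse(s >= 0, model$class_labels[1], model$class_labels[2]))
  }
  proj <- x %*% model$P
  dists <- vapply(
    seq_along(model$class_labels),
    function(j) rowSums(sweep(proj, 2, model$means_projected[, j])^2),
    numeric(nrow(proj))
  )
  dists <- matrix(dists, nrow = nrow(proj))
  model$class_labels[max.col(-dists, ties.method = "first")]
}

#' @rdname classify
#' @param object A fitted `frp_fda`.
#' @param newdata Matrix of observations.
#' @param type `"class"`, `"score"` (binary only) or `"projection"`.
#' @param ... Unused.
#' @export
predict.frp_fda <- function(object, newdata,
                            type = c("class", "score", "projection"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  switch(type,
    class = classify(object, newdata),
    score = decision_scores(object, newdata),
    projection = newdata %*% object$P
  )
}
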
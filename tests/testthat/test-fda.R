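test_that("scatter matrices reproduce the hand-computed 1-D example", {
  # class A = {0, 2}, class B = {4, 6}: mu_A = 1, mu_B = 5, mu = 3
  x <- c(0, 2, 4, 6)
  labs <- c("A", "A", "B", "B")
  sc <- scatter_matrices(x, labs)
  expect_equal(sc$S_b[1, 1], 2 * (1 - 3)^2 + 2 * (5 - 3)^2) # 16
  expect_equal(sc$S_w[1, 1], (0 - 1)^2 + (2 - 1)^2 + (4 - 5)^2 + (6 - 5)^2) # 4
  expect_equal(unname(sc$class_means[1, ]), c(1, 5))
  expect_equal(unname(sc$mu), 3)
})

test_that("scatter matrices: degenerate and invariance cases", {
  set.seed(1)
  x <- matrix(rnorm(40 * 3), 40)
  labs <- rep(c("a", "b"), each = 20)
  # identical class means -> S_b = 0
  x0 <- rbind(x[1:20, ], x[1:20, ])
  sc0 <- scatter_matrices(x0, labs)
  expect_lt(max(abs(sc0$S_b)), 1e-10)
  # permutation invariance
  perm <- sample(40)
  sc1 <- scatter_matrices(x, labs)
  sc2 <- scatter_matrices(x[perm, ], labs[perm])
  expect_equal(sc1$S_b, sc2$S_b)
  expect_equal(sc1$S_w, sc2$S_w)
  # class with < 2 samples
  expect_error(scatter_matrices(x, c("a", rep("b", 39))), ">= 2 samples")
})

test_that("shrinkage boundaries and arithmetic are exact", {
  s <- diag(c(2, 4))
  expect_identical(shrink_covariance(s, 0), s)
  expect_equal(shrink_covariance(s, 1), diag(c(3, 3)))
  expect_equal(shrink_covariance(s, 0.5), diag(c(2.5, 3.5)))
  expect_error(shrink_covariance(s, 1.5), "\\[0, 1\\]")

  # rank-deficient input becomes positive definite for every lambda > 0
  set.seed(2)
  a <- matrix(rnorm(10 * 2), 10)
  s_def <- crossprod(a %*% matrix(rnorm(2 * 10), 2)) # rank 2 in 10 dims
  for (lam in c(1e-3, 0.1, 0.5, 1)) {
    ev <- eigen(shrink_covariance(s_def, lam), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("analytic shrinkage intensity behaves like a consistent estimator", {
  set.seed(3)
  # n >> d, well-conditioned anisotropic covariance: almost no shrinkage
  # needed (for isotropic data the equal-diagonal target is the truth and
  # lambda correctly tends to 1 instead)
  x <- matrix(rnorm(5000 * 5), 5000) %*% diag(sqrt(1:5))
  labs <- rep(c("a", "b"), length.out = 5000)
  expect_lt(estimate_shrinkage_intensity(x, labs), 0.1)
  xi <- matrix(rnorm(5000 * 5), 5000)
  expect_gt(estimate_shrinkage_intensity(xi, labs), 0.5)

  # n < d: lambda bounded away from 0 and shrunk covariance invertible
  for (seed in 1:20) {
    set.seed(seed)
    xs <- matrix(rnorm(15 * 30), 15)
    ls <- rep(c("a", "b"), length.out = 15)
    lam <- estimate_shrinkage_intensity(xs, ls)
    expect_gt(lam, 0.05)
    sc <- scatter_matrices(xs, ls)
    sig <- shrink_covariance(sc$S_w / (15 - 2), lam)
    expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  # constant features are fully shrunk
  expect_equal(estimate_shrinkage_intensity(matrix(1, 10, 3), rep(c("a", "b"), 5)), 1)
})

test_that("binary FDA weight matches closed form and brute-force oracle", {
  set.seed(4)
  # isotropic classes: w parallel to the mean difference
  n <- 400
  mu <- c(3, -1, 2)
  x <- rbind(
    matrix(rnorm(n * 3), n),
    matrix(rnorm(n * 3), n) + rep(mu, each = n)
  )
  labs <- rep(c("a", "b"), each = n)
  m <- fit_fda(x, labs)
  cosang <- abs(sum(m$w * mu) / sqrt(sum(m$w^2) * sum(mu^2)))
  expect_gte(cosang, 0.99)

  # small instance: brute-force maximisation of the Rayleigh quotient
  set.seed(7)
  xs <- rbind(
    matrix(rnorm(20 * 3), 20) %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3),
    matrix(rnorm(20 * 3), 20) + rep(c(1.5, -1, 0.5), each = 20)
  )
  ls <- rep(c("a", "b"), each = 20)
  model <- fit_fda(xs, ls)
  sc <- scatter_matrices(xs, ls)
  sigma <- shrink_covariance(sc$S_w / (40 - 2), model$lambda)
  dirs <- matrix(rnorm(3 * 2e5), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  quot <- rowSums((dirs %*% sc$S_b) * dirs) / rowSums((dirs %*% sigma) * dirs)
  best <- dirs[which.max(quot), ]
  ang <- acos(min(1, abs(sum(best * model$w) / sqrt(sum(model$w^2))))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("collinear class means give an effectively rank-1 discriminant", {
  set.seed(5)
  base <- matrix(rnorm(60 * 4), 60)
  shift <- rep(c(0, 2, 4), each = 20) # means along one line
  x <- base + outer(shift, c(1, 0, 0, 0))
  labs <- rep(c("a", "b", "c"), each = 20)
  m <- fit_fda(x, labs)
  expect_lt(m$eigenvalues[2], 0.05 * m$eigenvalues[1])
})

test_that("decision scores: midpoint zero, antisymmetry, class ordering", {
  set.seed(6)
  x <- rbind(matrix(rnorm(50 * 2), 50), matrix(rnorm(50 * 2), 50) + 4)
  labs <- rep(c("a", "b"), each = 50)
  m <- fit_fda(x, labs)
  mid <- (m$class_means[, 1] + m$class_means[, 2]) / 2
  expect_equal(decision_scores(m, mid), 0, tolerance = 1e-10)

  flipped <- m
  flipped$w <- -m$w
  flipped$b <- -m$b
  expect_equal(decision_scores(flipped, x), -decision_scores(m, x))

  s <- decision_scores(m, x)
  expect_gt(mean(s[labs == "a"]), mean(s[labs == "b"]))

  m3 <- fit_fda(cbind(x, rnorm(100)), rep(c("a", "b", "c"), length.out = 100))
  expect_error(decision_scores(m3, cbind(x, 0)), "binary")
})

test_that("classification: sign rule, nearest projected mean, separable accuracy", {
  set.seed(7)
  x <- rbind(matrix(rnorm(50 * 2), 50), matrix(rnorm(50 * 2), 50) + 5)
  labs <- rep(c("a", "b"), each = 50)
  m <- fit_fda(x, labs)
  s <- decision_scores(m, x)
  expect_equal(classify(m, x), ifelse(s >= 0, "a", "b"))

  # three well-separated classes
  mu3 <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  x3 <- matrix(rnorm(300 * 3), 300) + mu3[rep(1:3, each = 100), ]
  l3 <- rep(c("a", "b", "c"), each = 100)
  m3 <- fit_fda(x3, l3)
  expect_gte(mean(classify(m3, x3) == l3), 0.95)
  # a sample at a class mean gets that class
  expect_equal(classify(m3, m3$class_means[, 2]), "b")
})

test_that("FDA invariants: scaling, Eq residual, shrinkage path, binary consistency", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60 * 5), 60), matrix(rnorm(60 * 5), 60) + 1.5)
  labs <- rep(c("a", "b"), each = 60)

  m <- fit_fda(x, labs)
  m_scaled <- fit_fda(7.3 * x, labs)
  expect_equal(classify(m, x), classify(m_scaled, 7.3 * x))

  # generalized eigenvalue residual for retained pairs
  resid <- m$S_b %*% m$P - m$Sigma_star %*% m$P %*% diag(m$eigenvalues, ncol(m$P))
  expect_lt(max(abs(resid)), 1e-8 * norm(m$S_b, "F"))

  # continuity of the shrinkage path: no NaNs, predictions stabilise
  preds <- lapply(seq(0.01, 1, by = 0.11), function(lam) {
    mm <- fit_fda(x, labs, lambda = lam)
    expect_false(any(is.na(mm$w)))
    classify(mm, x)
  })
  agree <- vapply(
    seq_len(length(preds) - 1),
    function(i) mean(preds[[i]] == preds[[i + 1]]), numeric(1)
  )
  expect_gt(min(agree), 0.9)

  # for two classes the multi-class path gives identical labels
  proj <- x %*% m$P
  d_a <- (proj - m$means_projected[, "a"])^2
  d_b <- (proj - m$means_projected[, "b"])^2
  multi <- ifelse(d_a <= d_b, "a", "b")
  expect_equal(unname(multi[, 1]), classify(m, x))

  # forcing lambda = 0 on singular data raises with guidance
  xs <- matrix(rnorm(10 * 30), 10)
  expect_error(
    fit_fda(xs, rep(c("a", "b"), 5), lambda = 0),
    "shrinkage"
  )
})

test_that("tidy and glance summarise discriminant models", {
  set.seed(9)
  x <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4), 30) + 2)
  m <- fit_fda(x, rep(c("a", "b"), each = 30))
  td <- tidy(m)
  expect_equal(td$label, c("a", "b"))
  expect_equal(td$n, c(30L, 30L))
  gl <- glance(m)
  expect_equal(gl$n_classes, 2)
  expect_true(gl$lambda >= 0 && gl$lambda <= 1)
})
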
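test_that("PCA explained variance matches an eigendecomposition oracle", {
  set.seed(91)
  # rank-1 matrix: first component explains everything
  X1 <- tcrossprod(rnorm(8), rnorm(5))
  expect_equal(fit_pca(X1, 1)$explained, 1, tolerance = 1e-12)

  # 2x2 identity as a pre-scaled input: two equal components of 50%
  expect_equal(fit_pca(diag(2), 1)$explained, 0.5, tolerance = 1e-12)

  # random matrix vs dense eigensolver of the cross-product
  X <- matrix(rnorm(200), 20, 10)
  pc <- fit_pca(X, 10)
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$explained, ev / sum(ev), tolerance = 1e-10)
  # exact reconstruction from all components
  expect_equal(pc$scores %*% t(pc$loadings), X, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_pca(X, 20), "exceeds")
})

test_that("OPLS-DA recovers a perfect single predictor", {
  y <- rep(c("a", "b"), each = 10)
  yv <- ifelse(y == "b", 1, -1)
  set.seed(101)
  X <- cbind(yv, matrix(rnorm(20 * 4, sd = 0.05), 20, 4))
  fit <- fit_oplsda(X, y, n_orth = 0)
  expect_gt(fit$r2y, 0.99)
  expect_identical(which.max(fit$vip), 1L)
  expect_gt(cross_validated_q2(X, y), 0.99)

  # p = 1: the single feature has VIP exactly 1
  f1 <- fit_oplsda(matrix(yv + rnorm(20, sd = 0.1), ncol = 1), y)
  expect_equal(f1$vip, 1, tolerance = 1e-12)

  expect_error(fit_oplsda(cbind(X, 0), y), "constant")
  expect_error(fit_oplsda(X, rep("a", 20)), "two classes")
})

test_that("VIP follows its formula and normalization", {
  # two features proportional to y with weights (0.8, 0.6):
  # VIP = sqrt(2) * (0.8, 0.6)
  y <- rep(c("a", "b"), each = 6)
  yv <- ifelse(y == "b", 1, -1)
  fit <- fit_oplsda(cbind(0.8 * yv, 0.6 * yv), y)
  expect_equal(fit$vip, c(sqrt(2) * 0.8, sqrt(2) * 0.6), tolerance = 1e-6)
  expect_equal(compute_vip(fit), fit$vip)

  # identical features: all VIP exactly 1
  Xi <- matrix(rep(yv + c(rnorm(12, sd = 0.5)), 4), ncol = 4)
  expect_equal(fit_oplsda(Xi, y)$vip, rep(1, 4), tolerance = 1e-10)

  # sum VIP^2 = p on arbitrary fits
  for (s in 1:5) {
    X <- random_problem(s)
    y2 <- rep(c("a", "b"), length.out = nrow(X))
    for (no in 0:2) {
      f <- fit_oplsda(X, y2, n_orth = no)
      expect_equal(sum(f$vip^2), ncol(X), tolerance = 1e-8)
    }
  }
})

test_that("predictive and orthogonal structure is orthogonal and conservative", {
  for (s in 1:5) {
    X <- random_problem(s, n = 30, p = 15)
    y <- rep(c("a", "b"), length.out = 30)
    f <- fit_oplsda(X, y, n_orth = 2)
    # score orthogonality
    for (k in seq_len(ncol(f$scores_orth)))
      expect_lt(abs(crossprod(f$scores, f$scores_orth[, k])), 1e-8)
    # variance bookkeeping: modelled + residual = total
    Xhat <- tcrossprod(f$scores, f$loadings) +
      tcrossprod(f$scores_orth, f$loadings_orth)
    resid_ss <- sum((X - Xhat)^2)
    expect_equal(f$r2x + resid_ss / sum(X^2), 1, tolerance = 1e-8)
  }
})

test_that("OPLS-DA with no orthogonal components equals 1-component PLS-DA", {
  X <- random_problem(7, n = 26, p = 10)
  y <- rep(c("a", "b"), length.out = 26)
  fo <- fit_oplsda(X, y, n_orth = 0)
  fp <- fit_plsda(X, y, k = 1)
  expect_equal(as.vector(fo$scores), as.vector(fp$scores), tolerance = 1e-8)
  expect_equal(fo$r2y, fp$r2y, tolerance = 1e-10)
  expect_equal(fo$vip, fp$vip, tolerance = 1e-10)
})

test_that("PLS-DA predictive scores agree with an established implementation", {
  skip_if_not_installed("mixOmics")
  X <- random_problem(8, n = 24, p = 9)
  y <- rep(c("a", "b"), length.out = 24)
  fp <- fit_plsda(X, y, k = 2)
  mo <- mixOmics::pls(X, ifelse(y == "b", 1, -1), ncomp = 2,
                      mode = "regression", scale = FALSE)
  for (k in 1:2)
    expect_gt(abs(cor(fp$scores[, k], mo$variates$X[, k])), 1 - 1e-8)
})

test_that("Q2 behaves like a cross-validated optimism-corrected R2Y", {
  # Q2 <= R2Y on fitted datasets
  for (s in 1:5) {
    X <- random_problem(s, n = 28, p = 14)
    y <- rep(c("a", "b"), length.out = 28)
    f <- fit_oplsda(X, y)
    expect_lte(cross_validated_q2(X, y), f$r2y + 1e-6)
  }
  # pure noise: Q2 <= 0 in at least 90% of replicates (n = 60, p = 50)
  neg <- 0L
  for (s in 1:50) {
    set.seed(200 + s)
    Xn <- scale(matrix(rnorm(60 * 50), 60, 50), scale = FALSE)
    yn <- rep(c("a", "b"), each = 30)
    if (cross_validated_q2(Xn, yn) <= 0) neg <- neg + 1L
  }
  expect_gte(neg, 45L)
})

test_that("permutation testing reports the exceedance convention", {
  X <- random_problem(9, n = 24, p = 10, effect = 3)
  y <- rep(c("a", "b"), length.out = 24)
  pr <- permutation_test(X, y, n_perm = 100, statistic = "Q2", seed = 5)
  expect_identical(pr$n_exceeding, 0L)
  expect_equal(pr$p_raw, 0)
  expect_equal(pr$p_value, 1 / 101)
  expect_output(print(pr), "0/100")

  # label-independent data: observed statistic is unremarkable
  Xn <- random_problem(10, n = 24, p = 10, effect = 0)
  prn <- permutation_test(Xn, y, n_perm = 49, statistic = "R2Y", seed = 6)
  expect_gt(prn$p_value, 0.05)
})

test_that("orthogonal component selection maximizes Q2 under a cap", {
  X <- random_problem(11, n = 30, p = 12)
  y <- rep(c("a", "b"), length.out = 30)
  sel <- select_n_orth(X, y, max_orth = 3)
  expect_identical(length(sel$q2_by_n_orth), 4L)
  expect_equal(sel$q2, max(sel$q2_by_n_orth))
  expect_equal(unname(sel$q2_by_n_orth[sel$n_orth + 1]), sel$q2)
})
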
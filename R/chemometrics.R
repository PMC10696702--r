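# Latent-variable discrimination engine: PCA, PLS-DA and OPLS-DA fitted by
# NIPALS-style algorithms on pre-scaled matrices (log + Pareto upstream).
# With a univariate response the PLS weight vector is available in closed
# form per component, so fitting is deterministic -- no RNG is involved.

code_y <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must have exactly two classes")
  yc <- ifelse(f == levels(f)[2], 1, -1)
  list(y = yc - mean(yc), mean = mean(yc), levels = levels(f))
}

check_X <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be complete and finite")
  if (any(apply(X, 2, var) == 0))
    stop("constant column in X; Pareto-scale upstream")
  X
}

#' Principal component analysis of a scaled matrix
#'
#' Singular value decomposition of the (already centred/scaled) matrix; no
#' further centring is applied. Explained-variance fractions are
#' non-increasing and reconstructing from all components returns the matrix
#' exactly.
#'
#' @param X scaled numeric matrix (samples x features).
#' @param k number of components, `k <= min(n - 1, p)`.
#' @return list with `scores` (n x k), `loadings` (p x k),
#'   `explained` (length-k fractions of total variance), `total_ss`.
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  if (k > min(nrow(X) - 1, ncol(X)))
    stop("k exceeds min(n - 1, p)")
  sv <- svd(X, nu = k, nv = k)
  total <- sum(X^2)
  list(scores = sv$u %*% diag(sv$d[seq_len(k)], k, k),
       loadings = sv$v,
       explained = sv$d[seq_len(k)]^2 / total,
       total_ss = total)
}

#' PLS-DA (univariate-response partial least squares) fit
#'
#' NIPALS PLS1 with successive deflation of X and y. Used for the
#' multi-component score plots and explained-variance reporting; the
#' discrimination models themselves use [fit_oplsda()].
#'
#' @param X scaled matrix; @param y two-level class labels;
#' @param k number of components.
#' @return list of class `plsda_model`: `scores`, `weights`, `loadings`,
#'   `y_loadings`, `r2x` (per-component X-variance fractions), `r2y`
#'   (cumulative), `ssy` (per-component explained y sum of squares), `vip`.
#' @export
fit_plsda <- function(X, y, k = 2) {
  X <- check_X(X); yc <- code_y(y)
  ycur <- yc$y; Xcur <- X
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, k); Tm <- matrix(0, n, k); cvec <- numeric(k)
  total_x <- sum(X^2); ss_y <- sum(yc$y^2)
  for (a in seq_len(k)) {
    w <- crossprod(Xcur, ycur)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k <- a - 1L; break }
    w <- w / nw
    t <- Xcur %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xcur, t) / tt
    cc <- sum(ycur * t) / tt
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; cvec[a] <- cc
    Xcur <- Xcur - tcrossprod(t, pvec)
    ycur <- ycur - cc * t
  }
  idx <- seq_len(k)
  ssy_comp <- cvec[idx]^2 * colSums(Tm[, idx, drop = FALSE]^2)
  r2x <- vapply(idx, function(a)
    sum(tcrossprod(Tm[, a], P[, a])^2) / total_x, numeric(1))
  structure(list(scores = Tm[, idx, drop = FALSE],
                 weights = W[, idx, drop = FALSE],
                 loadings = P[, idx, drop = FALSE],
                 y_loadings = cvec[idx],
                 r2x = r2x, r2y = sum(ssy_comp) / ss_y,
                 ssy = ssy_comp, ss_y_total = ss_y,
                 vip = vip_from_weights(W[, idx, drop = FALSE], ssy_comp),
                 y_mean = yc$mean, y_levels = yc$levels),
            class = "plsda_model")
}

#' OPLS-DA fit
#'
#' Orthogonal projections to latent structures discriminant analysis: the
#' requested number of y-orthogonal components is removed from X first
#' (each built from the part of the X-loading not aligned with the
#' y-predictive weight), then a single predictive component is fitted on the
#' filtered matrix. With `n_orth = 0` the model degenerates to one-component
#' PLS-DA. The class response is coded +/-1 and centred.
#'
#' @param X scaled matrix (samples x features), no constant columns.
#' @param y two-level class labels.
#' @param n_orth number of orthogonal components (`>= 0`). Extraction stops
#'   early if no orthogonal variation remains.
#' @return object of class `opls_model` with predictive
#'   `scores`/`weights`/`loadings`, orthogonal
#'   `scores_orth`/`weights_orth`/`loadings_orth`, `y_loading`, `r2x`
#'   (cumulative fraction of X variance captured by all components), `r2y`,
#'   `vip`, `n_components = c(predictive = 1, orthogonal = n_orth_used)`.
#'   `q2` is `NA` until filled by [cross_validated_q2()].
#' @export
fit_oplsda <- function(X, y, n_orth = 0) {
  X <- check_X(X); yc <- code_y(y)
  yv <- yc$y
  n <- nrow(X); p <- ncol(X)
  total_x <- sum(X^2)
  Wo <- Po <- matrix(0, p, 0); To <- matrix(0, n, 0)
  Xcur <- X
  for (o in seq_len(n_orth)) {
    w <- crossprod(Xcur, yv); w <- w / sqrt(sum(w^2))
    t <- Xcur %*% w
    pvec <- crossprod(Xcur, t) / sum(t^2)
    w_o <- pvec - as.numeric(crossprod(w, pvec)) * w
    if (sqrt(sum(w_o^2)) < 1e-10) break
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- Xcur %*% w_o
    p_o <- crossprod(Xcur, t_o) / sum(t_o^2)
    Wo <- cbind(Wo, w_o); Po <- cbind(Po, p_o); To <- cbind(To, t_o)
    Xcur <- Xcur - tcrossprod(t_o, p_o)
  }
  w <- crossprod(Xcur, yv)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("no y-covariant variation left in X")
  w <- w / nw
  t <- Xcur %*% w
  tt <- sum(t^2)
  pvec <- crossprod(Xcur, t) / tt
  cc <- sum(yv * t) / tt
  resid <- Xcur - tcrossprod(t, pvec)
  ssy_comp <- cc^2 * tt
  structure(list(
    scores = t, weights = w, loadings = pvec,
    scores_orth = To, weights_orth = Wo, loadings_orth = Po,
    y_loading = cc,
    r2x = 1 - sum(resid^2) / total_x,
    r2y = ssy_comp / sum(yv^2),
    q2 = NA_real_,
    vip = vip_from_weights(w, ssy_comp),
    n_components = c(predictive = 1L, orthogonal = ncol(To)),
    y_mean = yc$mean, y_levels = yc$levels),
    class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> 1 predictive + ", x$n_components["orthogonal"],
      " orthogonal component(s)\n", sep = "")
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %s\n", x$r2x, x$r2y,
              if (is.na(x$q2)) "NA (run cross_validated_q2)" else
                sprintf("%.3f", x$q2)))
  invisible(x)
}

#' Predict scores and class values for new samples
#'
#' Orthogonal variation is removed from the new rows with the fitted
#' orthogonal weights/loadings, then the predictive score and fitted class
#' value are computed.
#'
#' @param object an `opls_model`; @param newdata matrix on the training
#'   scale; @param ... unused.
#' @return list with `score` and `yhat` (on the centred +/-1 scale plus the
#'   training class mean).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  E <- as.matrix(newdata)
  ko <- ncol(object$scores_orth)
  for (o in seq_len(ko)) {
    t_o <- E %*% object$weights_orth[, o]
    E <- E - tcrossprod(t_o, object$loadings_orth[, o])
  }
  t <- E %*% object$weights
  list(score = as.vector(t),
       yhat = as.vector(t) * object$y_loading + object$y_mean)
}

# VIP from predictive weight matrix (p x A, columns unit norm) and the
# explained y sum of squares per component. Sum of squared VIPs equals p.
vip_from_weights <- function(W, ssy) {
  p <- nrow(W)
  if (sum(ssy) == 0) return(rep(NA_real_, p))
  as.vector(sqrt(p * (W^2 %*% ssy) / sum(ssy)))
}

#' VIP scores of a fitted model
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` over the predictive
#' components, with unit-norm weight vectors; the squared VIPs average 1 so
#' `sum_j VIP_j^2 = p`, and VIP > 1 flags features contributing more than an
#' average feature.
#'
#' @param model a fitted `opls_model` or `plsda_model`.
#' @return numeric vector of per-feature VIP scores.
#' @export
compute_vip <- function(model) {
  if (inherits(model, "opls_model"))
    return(vip_from_weights(model$weights, model$r2y))
  if (inherits(model, "plsda_model"))
    return(vip_from_weights(model$weights, model$ssy))
  stop("not a fitted model")
}

# Deterministic stratified fold assignment: within each class, samples are
# dealt to folds in round-robin order.
stratified_folds <- function(y, folds) {
  f <- factor(y)
  fold <- integer(length(y))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    if (length(idx) < 2)
      stop("class ", lv, " has fewer than 2 samples; cannot stratify")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Stratified k-fold cross-validation of an OPLS-DA model:
#' `Q2 = 1 - PRESS / SS_tot`, where PRESS accumulates squared prediction
#' errors of the held-out samples (each fold's model refitted from scratch)
#' and SS_tot is the total sum of squares of the centred class response.
#' The fitted `q2` slot of a model can be filled with the returned value.
#'
#' @param X scaled matrix; @param y two-level labels;
#' @param folds number of folds (default 7); each training split retains
#'   both classes by stratified assignment.
#' @param n_orth orthogonal components for each refit.
#' @return Q2 (can be negative when the model predicts worse than the mean).
#' @export
cross_validated_q2 <- function(X, y, folds = 7, n_orth = 0) {
  X <- as.matrix(X)
  if (folds < 2) stop("folds must be >= 2")
  yc <- code_y(y)
  folds <- min(folds, min(table(y)))
  fold <- stratified_folds(y, folds)
  press <- 0
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- fit_oplsda(X[!test, , drop = FALSE], y[!test], n_orth = n_orth)
    yhat <- predict(fit, X[test, , drop = FALSE])$yhat
    ytest <- ifelse(factor(y[test], levels = yc$levels) == yc$levels[2],
                    1, -1) - yc$mean
    press <- press + sum((ytest - (yhat - yc$mean))^2)
  }
  1 - press / sum(yc$y^2)
}

#' Choose the number of orthogonal components by Q2
#'
#' Evaluates `n_orth = 0 .. max_orth` and returns the first maximiser of the
#' cross-validated Q2.
#'
#' @inheritParams cross_validated_q2
#' @param max_orth cap on orthogonal components (default 5).
#' @return list with `n_orth`, `q2` (the maximum), `q2_by_n_orth`.
#' @export
select_n_orth <- function(X, y, max_orth = 5, folds = 7) {
  q2s <- vapply(0:max_orth, function(k)
    cross_validated_q2(X, y, folds = folds, n_orth = k), numeric(1))
  best <- which.max(q2s)
  list(n_orth = best - 1L, q2 = q2s[best],
       q2_by_n_orth = setNames(q2s, 0:max_orth))
}

#' Permutation test of an OPLS-DA model statistic
#'
#' Class labels are permuted uniformly `n_perm` times and the model statistic
#' (cross-validated Q2 or fitted R2Y) recomputed each time. The exceedance
#' count (permuted >= observed) is reported both in the conventional raw form
#' `k/n` (so a fully separated model reads "0/100", i.e. p < 0.01) and as the
#' unbiased permutation p-value `(k + 1) / (n + 1)`.
#'
#' @inheritParams cross_validated_q2
#' @param n_perm number of permutations (default 100).
#' @param statistic `"Q2"` or `"R2Y"`.
#' @param seed integer seed for the permutations.
#' @return object of class `permutation_result`: `observed`,
#'   `n_permutations`, `n_exceeding`, `p_raw = k/n`,
#'   `p_value = (k+1)/(n+1)`, `perm_stats`.
#' @export
permutation_test <- function(X, y, n_perm = 100, statistic = c("Q2", "R2Y"),
                             folds = 7, n_orth = 0, seed = 1L) {
  statistic <- match.arg(statistic)
  stat_fun <- function(yy) {
    if (statistic == "Q2")
      cross_validated_q2(X, yy, folds = folds, n_orth = n_orth)
    else fit_oplsda(X, yy, n_orth = n_orth)$r2y
  }
  observed <- stat_fun(y)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat_fun(sample(y)), numeric(1)))
  k <- sum(perm >= observed)
  structure(list(observed = observed, statistic = statistic,
                 n_permutations = n_perm, n_exceeding = k,
                 p_raw = k / n_perm, p_value = (k + 1) / (n_perm + 1),
                 perm_stats = perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed %.3f, exceedances %d/%d, p = %.4f\n",
              x$statistic, x$observed, x$n_exceeding, x$n_permutations,
              x$p_value))
  invisible(x)
}
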
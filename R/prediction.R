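# Logistic prediction models with ROC/AUC and DeLong confidence intervals.

#' Fit a logistic prediction model and its ROC curve
#'
#' Maximum-likelihood logistic regression of case status on the given
#' features; in-sample predicted probabilities feed the ROC. Complete
#' separation is flagged (the fit is still returned with a warning since
#' the in-sample ranking remains valid).
#'
#' @param features numeric matrix or data.frame (samples x predictors), no
#'   constant columns.
#' @param labels two-level class labels (second factor level = positive).
#' @return object of class `prediction_result`: `coefficients`, `prob`
#'   (per-sample predicted probability), `roc` (points), `auc`, `auc_ci`,
#'   `separation`.
#' @export
fit_predict_logistic <- function(features, labels) {
  X <- as.data.frame(features)
  f <- factor(labels)
  if (nlevels(f) != 2) stop("both classes must be present")
  if (any(vapply(X, function(c) var(as.numeric(c)) == 0, TRUE)))
    stop("constant feature in the model matrix")
  y <- as.integer(f == levels(f)[2])
  fit <- suppressWarnings(glm(y ~ ., binomial(), data = cbind(y = y, X)))
  mu <- fit$fitted.values
  sep <- any(mu > 1 - 1e-8 & y == 1) && any(mu < 1e-8 & y == 0)
  if (sep) warning("complete separation detected; coefficients diverge")
  roc <- roc_auc(mu, y)
  ci <- auc_ci(mu, y)
  structure(list(coefficients = coef(fit), prob = mu, labels = y,
                 roc = roc$points, auc = roc$auc, auc_ci = ci,
                 separation = sep, model = fit),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d predictors; AUC = %.3f (95%% CI %.3f-%.3f)%s\n",
              length(x$coefficients) - 1, x$auc, x$auc_ci[1], x$auc_ci[2],
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps all observed score thresholds, computing sensitivity and
#' 1-specificity, and integrates by the trapezoid rule. The result equals
#' the pairwise concordance probability (ties counted 1/2), i.e. the
#' Mann-Whitney U statistic divided by `n1 * n2`.
#'
#' @param scores numeric risk scores; @param labels two-level labels
#'   (second level / nonzero = positive).
#' @return list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`, monotone nondecreasing).
#' @export
roc_auc <- function(scores, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("both classes must be present")
  y <- f == levels(f)[2]
  n1 <- sum(y); n0 <- sum(!y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc,
       points = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

# DeLong placement-value variance of the AUC.
delong_var <- function(scores, y) {
  sx <- scores[y]; sy <- scores[!y]
  m <- length(sx); n <- length(sy)
  v10 <- vapply(sx, function(s) mean((s > sy) + 0.5 * (s == sy)), numeric(1))
  v01 <- vapply(sy, function(s) mean((sx > s) + 0.5 * (sx == s)), numeric(1))
  var(v10) / m + var(v01) / n
}

#' Confidence interval for the AUC
#'
#' DeLong variance estimate with a normal-approximation interval truncated
#' to `[0, 1]`. When the DeLong variance degenerates to zero (e.g. complete
#' separation with a clear margin), a seeded stratified bootstrap
#' (percentile interval, 2000 resamples) is used instead.
#'
#' @param scores,labels as in [roc_auc()].
#' @param level confidence level (default 0.95).
#' @param boot_n bootstrap resamples for the fallback.
#' @param seed seed for the bootstrap fallback.
#' @return length-2 vector `c(low, high)` with attribute `method`.
#' @export
auc_ci <- function(scores, labels, level = 0.95, boot_n = 2000, seed = 1L) {
  f <- factor(labels)
  y <- f == levels(f)[2]
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 samples per class")
  auc <- roc_auc(scores, labels)$auc
  v <- delong_var(scores, y)
  if (v > 0) {
    zq <- qnorm(1 - (1 - level) / 2)
    ci <- c(auc - zq * sqrt(v), auc + zq * sqrt(v))
    method <- "delong"
  } else {
    idx1 <- which(y); idx0 <- which(!y)
    boots <- with_seed(seed, vapply(seq_len(boot_n), function(b) {
      i1 <- sample(idx1, length(idx1), replace = TRUE)
      i0 <- sample(idx0, length(idx0), replace = TRUE)
      roc_auc(scores[c(i1, i0)], y[c(i1, i0)])$auc
    }, numeric(1)))
    ci <- unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
    method <- "bootstrap"
  }
  ci <- pmin(pmax(ci, 0), 1)
  attr(ci, "method") <- method
  ci
}

#' Multivariable covariate screen over selected metabolites
#'
#' Fits one multivariable logistic regression of a binary covariate (e.g.
#' current smoking) on all features jointly and reports each feature's odds
#' ratio (per unit of the feature) with its Wald p-value. Used to check
#' whether selected biomarkers merely proxy the covariate.
#'
#' @param features numeric matrix/data.frame (samples x features).
#' @param covariate binary vector (0/1 or two-level factor).
#' @return data.frame `feature`, `or`, `beta`, `se`, `p`, plus a
#'   `separation` attribute.
#' @export
covariate_screen <- function(features, covariate) {
  X <- as.data.frame(features)
  f <- factor(covariate)
  if (nlevels(f) != 2) stop("covariate must be binary")
  y <- as.integer(f == levels(f)[2])
  fit <- suppressWarnings(glm(y ~ ., binomial(), data = cbind(y = y, X)))
  mu <- fit$fitted.values
  sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8) || !fit$converged
  cf <- summary(fit)$coefficients
  feats <- setdiff(rownames(cf), "(Intercept)")
  out <- data.frame(feature = feats, or = exp(cf[feats, 1]),
                    beta = cf[feats, 1], se = cf[feats, 2],
                    p = cf[feats, 4], stringsAsFactors = FALSE)
  attr(out, "separation") <- sep
  out
}
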
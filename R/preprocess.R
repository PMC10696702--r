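#' QC-detection feature filter
#'
#' Retains exactly the features whose detection fraction across QC
#' injections is at least `min_detect` (default 0.8: features detected in
#' less than 80% of QC injections are discarded). Feature order is
#' preserved; the operation is idempotent.
#'
#' @param table a [feature_table()] with `qc_detection` populated.
#' @param min_detect minimum detection fraction.
#' @return the filtered [feature_table()].
#' @export
qc_filter <- function(table, min_detect = 0.8) {
  if (is.null(table$qc_detection))
    stop("qc_detection is not populated on this feature table")
  keep <- table$qc_detection >= min_detect
  if (!any(keep))
    stop("no feature reaches the QC detection threshold ", min_detect)
  subset_features(table, which(keep))
}

#' Assay-precision (%RSD) report for QC replicates
#'
#' Per-feature relative standard deviation, `100 * sd / mean`, computed with
#' the sample standard deviation (denominator n - 1). Features with zero
#' mean have no defined RSD and are flagged as not computed.
#'
#' @param qc_replicates numeric matrix, replicate injections x features.
#' @param threshold acceptance threshold in percent (default 15: RSD <= 15%
#'   is conventionally acceptable precision for LC-MS assays).
#' @return data.frame with `feature`, `rsd`, `pass`, `computed`.
#' @export
rsd_report <- function(qc_replicates, threshold = 15) {
  qc_replicates <- as.matrix(qc_replicates)
  if (nrow(qc_replicates) < 2) stop("need at least 2 QC replicates")
  m <- colMeans(qc_replicates)
  s <- apply(qc_replicates, 2, sd)
  computed <- m != 0
  rsd <- ifelse(computed, 100 * s / m, NA_real_)
  data.frame(feature = colnames(qc_replicates) %||%
               sprintf("F%04d", seq_along(m)),
             rsd = rsd, pass = !is.na(rsd) & rsd <= threshold,
             computed = computed, stringsAsFactors = FALSE)
}

#' Impute missing abundances as half the per-feature observed minimum
#'
#' @param abund abundance matrix (samples x features).
#' @return matrix without missing values.
#' @export
impute_half_min <- function(abund) {
  for (j in seq_len(ncol(abund))) {
    miss <- is.na(abund[, j])
    if (any(miss)) {
      if (all(miss)) stop("feature ", j, " entirely missing; cannot impute")
      abund[miss, j] <- min(abund[!miss, j]) / 2
    }
  }
  abund
}

#' Log transform followed by Pareto scaling
#'
#' Missing values are imputed as half the per-feature minimum, abundances are
#' natural-log transformed, then each column is mean-centred and divided by
#' the square root of its standard deviation (Pareto scaling). Scaled columns
#' have mean 0 and variance equal to the pre-scaling standard deviation -- a
#' compromise between no scaling and unit-variance scaling that damps the
#' dominance of high-abundance metabolites without inflating noise.
#'
#' @param table a [feature_table()] or a bare abundance matrix.
#' @return the scaled matrix, with attributes `center` and `scale`
#'   (the per-column log-means and `sqrt(sd)` divisors).
#' @export
log_pareto <- function(table) {
  abund <- if (inherits(table, "feature_table")) table$abund else
    as.matrix(table)
  abund <- impute_half_min(abund)
  if (any(abund <= 0))
    stop("nonpositive abundances after imputation; cannot log transform")
  lx <- log(abund)
  ctr <- colMeans(lx)
  s <- apply(lx, 2, sd)
  if (any(s == 0)) {
    bad <- which(s == 0)
    stop("zero-variance feature(s) after log transform: ",
         paste(head(colnames(lx)[bad] %||% bad, 5), collapse = ", "))
  }
  out <- sweep(sweep(lx, 2, ctr), 2, sqrt(s), "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sqrt(s)
  out
}
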
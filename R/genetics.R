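#' Construct a genotype panel
#'
#' @param geno integer matrix of risk-allele counts (samples x SNPs, values
#'   0/1/2 or `NA` for missing), with row and column names.
#' @param samples optional data.frame of sample metadata (`sample_id`, ...).
#' @return An object of class `genotype_panel` with per-SNP missing rate,
#'   minor allele frequency and exact Hardy-Weinberg p-value, and per-sample
#'   missing rate.
#' @export
genotype_panel <- function(geno, samples = NULL) {
  geno <- as.matrix(geno)
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("allele counts must be 0, 1, 2 or NA")
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("snp%04d", seq_len(ncol(geno)))
  if (is.null(samples))
    samples <- data.frame(sample_id = rownames(geno) %||%
                            sprintf("S%04d", seq_len(nrow(geno))),
                          stringsAsFactors = FALSE)
  x <- structure(list(geno = geno, samples = samples), class = "genotype_panel")
  refresh_snp_stats(x)
}

refresh_snp_stats <- function(panel) {
  g <- panel$geno
  n_obs <- colSums(!is.na(g))
  af <- colSums(g, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    hwe_exact_test(sum(gj == 2L, na.rm = TRUE), sum(gj == 1L, na.rm = TRUE),
                   sum(gj == 0L, na.rm = TRUE))
  }, numeric(1))
  panel$snps <- data.frame(
    snp_id = colnames(g),
    missing_rate = 1 - n_obs / nrow(g),
    maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
  panel$sample_missing <- rowMeans(is.na(g))
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$geno), " samples x ", ncol(x$geno),
      " SNPs; median MAF ", signif(median(x$snps$maf), 3), "\n", sep = "")
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts (the PLINK
#' convention): the p-value sums the conditional probabilities of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts for minor-allele
#'   homozygotes, heterozygotes, major-allele homozygotes (orientation does
#'   not matter; it is inferred from the allele counts).
#' @return two-sided exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  if (n == 0L) return(1)
  n_minor <- min(2L * n_hom_minor + n_het, 2L * n_hom_major + n_het)
  if (n_minor == 0L) return(1)
  # possible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log conditional probability of each het count given allele counts
  logp <- lgamma(n + 1) -
    lgamma((n_minor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_minor + hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_het)
  if (length(obs) == 0L) stop("heterozygote count inconsistent with alleles")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' SNP and sample quality control
#'
#' Applies, in this documented order: (1) drop SNPs with missing rate above
#' `max_snp_missing`; (2) drop samples with missing rate above
#' `max_sample_missing` (computed on the SNPs surviving step 1); (3) drop
#' SNPs with minor allele frequency below `min_maf`; (4) drop SNPs whose
#' exact Hardy-Weinberg p-value is below `hwe_p_threshold`. Statistics are
#' recomputed after each step, so downstream filters see the filtered data.
#'
#' @param panel a [genotype_panel()].
#' @param max_snp_missing,max_sample_missing,min_maf,hwe_p_threshold QC
#'   thresholds (defaults 0.05, 0.05, 0.05, 1e-6).
#' @return the filtered [genotype_panel()] with a `qc_log` attribute giving
#'   per-filter removal counts.
#' @export
snp_qc <- function(panel, max_snp_missing = 0.05, max_sample_missing = 0.05,
                   min_maf = 0.05, hwe_p_threshold = 1e-6) {
  stopifnot(inherits(panel, "genotype_panel"), ncol(panel$geno) > 0)
  log <- c(snp_missing = 0L, sample_missing = 0L, maf = 0L, hwe = 0L)

  keep <- panel$snps$missing_rate <= max_snp_missing
  log["snp_missing"] <- sum(!keep)
  panel <- refresh_snp_stats(subset_panel(panel, snps = keep))

  keep_s <- panel$sample_missing <= max_sample_missing
  log["sample_missing"] <- sum(!keep_s)
  panel <- refresh_snp_stats(subset_panel(panel, samples = keep_s))

  keep <- panel$snps$maf >= min_maf
  log["maf"] <- sum(!keep)
  panel <- refresh_snp_stats(subset_panel(panel, snps = keep))

  keep <- panel$snps$hwe_p >= hwe_p_threshold
  log["hwe"] <- sum(!keep)
  panel <- refresh_snp_stats(subset_panel(panel, snps = keep))

  if (ncol(panel$geno) == 0)
    stop("all SNPs removed by QC (removed per filter: ",
         paste(names(log), log, sep = "=", collapse = ", "), ")")
  attr(panel, "qc_log") <- log
  panel
}

subset_panel <- function(panel, snps = NULL, samples = NULL) {
  if (!is.null(snps)) panel$geno <- panel$geno[, snps, drop = FALSE]
  if (!is.null(samples)) {
    panel$geno <- panel$geno[samples, , drop = FALSE]
    panel$samples <- panel$samples[samples, , drop = FALSE]
  }
  panel
}

#' Per-SNP age-adjusted logistic association scan
#'
#' Fits, for each SNP, `status ~ allele_count + age` by maximum likelihood
#' (additive coding) and reports the Wald test of the allele-count
#' coefficient. Samples with a missing genotype are dropped per SNP.
#' Complete separation is flagged and the p-value set missing.
#'
#' @param panel a [genotype_panel()].
#' @param status 0/1 case indicator aligned with the panel's samples.
#' @param age numeric covariate aligned with the panel's samples (or `NULL`
#'   for an unadjusted scan).
#' @return data.frame with `snp_id`, `beta`, `se`, `p`, `separation`.
#' @export
gwas_logistic <- function(panel, status, age = NULL) {
  g <- panel$geno
  stopifnot(length(status) == nrow(g))
  if (length(unique(status)) != 2L) stop("both classes must be present")
  out <- lapply(seq_len(ncol(g)), function(j) {
    ok <- !is.na(g[, j])
    df <- data.frame(y = status[ok], x = g[ok, j])
    if (!is.null(age)) df$age <- age[ok]
    fml <- if (is.null(age)) y ~ x else y ~ x + age
    fit <- suppressWarnings(glm(fml, binomial(), data = df))
    mu <- fit$fitted.values
    sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8) || !fit$converged
    cf <- summary(fit)$coefficients
    if (sep || !"x" %in% rownames(cf))
      data.frame(beta = if ("x" %in% rownames(cf)) cf["x", 1] else NA_real_,
                 se = NA_real_, p = NA_real_, separation = TRUE)
    else
      data.frame(beta = cf["x", 1], se = cf["x", 2], p = cf["x", 4],
                 separation = FALSE)
  })
  cbind(data.frame(snp_id = colnames(g), stringsAsFactors = FALSE),
        do.call(rbind, out))
}

#' Select GRS weights from an association scan
#'
#' Keeps SNPs below the selection p-value threshold and orients each to its
#' risk allele: a positive log-odds estimate means the counted allele is the
#' risk allele; a negative estimate flips the orientation (counts become
#' `2 - count`) so weights are always positive log odds.
#'
#' @param gwas result of [gwas_logistic()].
#' @param p_threshold selection threshold (default `5e-5`).
#' @return data.frame of class `grs_weights` with `snp_id`, `flip`,
#'   `weight`, `p`.
#' @export
grs_weights <- function(gwas, p_threshold = 5e-5) {
  sel <- gwas[!is.na(gwas$p) & gwas$p < p_threshold, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no SNP passed the selection threshold p < ", p_threshold)
  out <- data.frame(snp_id = sel$snp_id, flip = sel$beta < 0,
                    weight = abs(sel$beta), p = sel$p,
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_weights", "data.frame")
  out
}

#' Compute per-sample genetic risk scores
#'
#' `GRS_i = sum_j (risk allele count)_ij * weight_j`. Missing genotypes
#' contribute the mean imputed count `2 * (risk allele frequency)` times the
#' weight, with the frequency estimated from the panel.
#'
#' @param panel a [genotype_panel()].
#' @param weights a [grs_weights()] data.frame (or any data.frame with
#'   `snp_id`, `weight` and optional logical `flip`).
#' @return named numeric vector of scores.
#' @export
compute_grs <- function(panel, weights) {
  miss <- setdiff(weights$snp_id, colnames(panel$geno))
  if (length(miss) > 0)
    stop("weights refer to SNPs absent from the panel: ",
         paste(head(miss, 5), collapse = ", "))
  g <- panel$geno[, weights$snp_id, drop = FALSE]
  flip <- if ("flip" %in% names(weights)) weights$flip else
    rep(FALSE, nrow(weights))
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  raf <- colMeans(g, na.rm = TRUE) / 2
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- 2 * raf[j]
  setNames(as.vector(g %*% weights$weight), rownames(panel$geno))
}

#' Split samples into GRS-low and GRS-high groups
#'
#' Median split; values equal to the median go to the low group, so an even
#' sample without ties splits into equal halves.
#'
#' @param grs numeric vector of scores (length `>= 2`).
#' @return factor with levels `low`, `high`, same names as `grs`.
#' @export
split_by_grs <- function(grs) {
  stopifnot(length(grs) >= 2)
  m <- median(grs)
  grp <- factor(ifelse(grs <= m, "low", "high"), levels = c("low", "high"))
  if (all(grp == "low"))
    warning("all GRS values equal; high group is empty")
  names(grp) <- names(grs)
  grp
}

#' Write / read genotypes as PLINK-.raw-style TSV
#'
#' One row per sample: `sample_id` then one column per SNP with the allele
#' count (0/1/2) or `NA`.
#'
#' @param panel a [genotype_panel()].
#' @param path TSV path.
#' @export
write_genotypes <- function(panel, path) {
  out <- cbind(data.frame(sample_id = panel$samples$sample_id),
               as.data.frame(panel$geno))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(raw[, -1, drop = FALSE])
  rownames(geno) <- raw$sample_id
  genotype_panel(geno, samples = data.frame(sample_id = raw$sample_id,
                                            stringsAsFactors = FALSE))
}
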
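test_that("exact HWE test matches closed cases and a Monte Carlo oracle", {
  # perfect HWE proportions: the observed het count is modal, p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  # complete heterozygote deficit at 50/0/50: astronomically unlikely
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # monomorphic SNP: nothing to test
  expect_equal(hwe_exact_test(0, 0, 80), 1)

  # Monte Carlo allele-shuffling oracle at small n
  cases <- list(c(2, 8, 20), c(5, 5, 20), c(1, 12, 17), c(0, 6, 9))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 mc_hwe_p(cs[1], cs[2], cs[3]), tolerance = 0.01)
  }
})

test_that("SNP QC drops exactly the constructed violators, in order", {
  set.seed(181)
  n <- 200
  good <- rbinom(n, 2, 0.3)
  high_missing <- good; high_missing[1:12] <- NA        # 6% missing
  low_maf <- rbinom(n, 2, 0.02)                          # MAF ~0.02
  hwe_bad <- c(rep(0, 100), rep(2, 100))                 # no heterozygotes
  geno <- cbind(ok = good, miss = high_missing, rare = low_maf,
                hwe = hwe_bad)
  rownames(geno) <- paste0("s", 1:n)
  panel <- genotype_panel(geno)
  out <- snp_qc(panel)
  expect_identical(colnames(out$geno), "ok")
  log <- attr(out, "qc_log")
  expect_identical(unname(log["snp_missing"]), 1L)
  expect_identical(unname(log["maf"]), 1L)
  expect_identical(unname(log["hwe"]), 1L)
  # idempotent
  out2 <- snp_qc(out)
  expect_identical(out2$geno, out$geno)
  # exact-HWE-proportion SNP is kept
  hw <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  expect_identical(ncol(snp_qc(genotype_panel(cbind(a = hw)))$geno), 1L)
  # everything removed raises an informative error
  expect_error(snp_qc(genotype_panel(cbind(bad = low_maf))), "all SNPs")
})

test_that("logistic GWAS matches an independent Newton solve", {
  set.seed(191)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 52, 7)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * g + 0.01 * age))
  panel <- genotype_panel(cbind(snp = g))
  res <- gwas_logistic(panel, y, age)
  beta_oracle <- newton_logistic(cbind(g, age), y)
  expect_equal(res$beta, beta_oracle[2], tolerance = 1e-6)
  expect_false(res$separation)

  # null SNPs give uniform p-values
  set.seed(192)
  gn <- matrix(rbinom(n * 200, 2, 0.3), n, 200)
  yn <- rbinom(n, 1, 0.5)
  pn <- gwas_logistic(genotype_panel(gn), yn)$p
  expect_gt(ks.test(pn, "punif")$p.value, 0.01)

  # complete separation is flagged with missing p
  ysep <- as.integer(g >= 1)
  rsep <- gwas_logistic(panel, ysep)
  expect_true(rsep$separation)
  expect_true(is.na(rsep$p))
})

test_that("GRS computation follows the weighted allele-count formula", {
  geno <- rbind(s1 = c(1, 2), s2 = c(0, NA))
  colnames(geno) <- c("a", "b")
  panel <- genotype_panel(geno)
  w <- data.frame(snp_id = c("a", "b"), weight = c(0.5, 2.0))
  grs <- compute_grs(panel, w)
  expect_equal(unname(grs["s1"]), 1 * 0.5 + 2 * 2.0)
  # missing genotype imputed as 2 * risk allele frequency (here 2 * 1 = 2)
  expect_equal(unname(grs["s2"]), 0 * 0.5 + 2 * 1.0 * 2.0)
  # linearity: doubling weights doubles the score
  w2 <- transform(w, weight = weight * 2)
  expect_equal(compute_grs(panel, w2), 2 * grs)
  # all-zero weights: GRS identically 0
  expect_equal(unname(compute_grs(panel, transform(w, weight = 0))), c(0, 0))
  expect_error(compute_grs(panel, data.frame(snp_id = "zz", weight = 1)),
               "absent")
})

test_that("computed GRS tracks the generative linear predictor", {
  cfg <- small_cfg(seed = 201, n_snps = 40, n_risk_snps = 5)
  truth <- generate_study(cfg)$truth
  ref <- sim_reference_cohort(cfg, truth, n_cases = 250, n_controls = 250,
                              seed = 202)
  w <- data.frame(snp_id = colnames(ref$panel$geno)[truth$risk_snp_indices],
                  weight = truth$true_snp_weights[truth$risk_snp_indices])
  grs <- compute_grs(ref$panel, w)
  expect_gt(cor(grs, ref$lp), 0.9)
})

test_that("GRS selection recovers planted effects at reference scale", {
  # single causal SNP, log-OR 0.8, n = 500: beta within +/-0.25 and
  # p < 5e-5 in >= 16/20 replicates
  ok <- 0L
  for (r in 1:20) {
    set.seed(600 + r)
    n_pool <- 6000
    g <- matrix(rbinom(n_pool * 12, 2, 0.35), n_pool, 12)
    lp <- -0.56 + 0.8 * g[, 1]
    y <- rbinom(n_pool, 1, plogis(lp))
    idx <- c(sample(which(y == 1), 250), sample(which(y == 0), 250))
    panel <- genotype_panel(g[idx, , drop = FALSE])
    res <- gwas_logistic(panel, y[idx])
    if (!is.na(res$p[1]) && abs(res$beta[1] - 0.8) <= 0.25 &&
        res$p[1] < 5e-5) ok <- ok + 1L
  }
  expect_gte(ok, 16L)
})

test_that("median split defines GRS groups with ties to the low side", {
  g <- split_by_grs(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_warning(split_by_grs(c(1, 1, 1)), "empty")
  set.seed(211)
  v <- rnorm(50)
  sp <- split_by_grs(v)
  expect_gt(mean(v[sp == "high"]), mean(v[sp == "low"]))
})
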
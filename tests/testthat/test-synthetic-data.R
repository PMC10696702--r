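test_that("precision matrix construction gives the requested structure", {
  # empty graph: identity, no partial correlations
  om0 <- make_precision_matrix(6, density = 0, strength = 0.4, seed = 1)
  expect_equal(unclass(om0), diag(6), ignore_attr = TRUE)
  expect_equal(pcor_from_precision(om0), diag(6), ignore_attr = TRUE)

  # single edge at p = 3: implied pcor magnitude equals strength exactly
  om1 <- make_precision_matrix(3, density = 0.34, strength = 0.4, seed = 2)
  e <- attr(om1, "edges")
  expect_identical(nrow(e), 1L)
  pc <- pcor_from_precision(om1)
  expect_equal(abs(pc[e[1, 1], e[1, 2]]), 0.4, tolerance = 1e-12)

  # positive definiteness across a sweep of sizes/densities/strengths
  for (s in 1:10) {
    p <- sample(4:30, 1)
    om <- make_precision_matrix(p, runif(1, 0, 0.5), runif(1, 0, 0.8),
                                seed = s)
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # edges attribute is exactly the nonzero off-diagonal support
    supp <- which(om != 0 & upper.tri(om), arr.ind = TRUE)
    supp <- supp[order(supp[, 1], supp[, 2]), , drop = FALSE]
    expect_equal(unname(attr(om, "edges")), unname(supp), ignore_attr = TRUE)
  }
})

test_that("large-sample partial correlations converge to the implied values", {
  om <- make_precision_matrix(10, density = 0.2, strength = 0.4, seed = 3)
  implied <- pcor_from_precision(om)
  set.seed(99)
  X <- MASS::mvrnorm(50000, mu = rep(0, 10), Sigma = solve(om))
  est <- partial_correlations(X, shrinkage = 0)
  expect_lt(max(abs(est - implied)), 0.02)
})

test_that("generated studies are deterministic with exact group counts", {
  cfg <- small_cfg(seed = 7)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1$set1$abund, st2$set1$abund)
  expect_identical(st1$genotypes$geno, st2$genotypes$geno)
  expect_identical(st1$truth$true_precision, st2$truth$true_precision)

  expect_equal(as.vector(table(st1$set1$samples$group)), c(20, 20))
  expect_equal(as.vector(table(st1$set2$samples$group)), c(18, 18))
  expect_identical(nrow(st1$genotypes$geno), 76L)
})

test_that("planted biomarkers dominate the standardized mean differences", {
  hits <- 0L
  for (r in 1:20) {
    st <- generate_study(small_cfg(seed = 100 + r))
    la <- log(st$set1$abund)
    grp <- st$set1$samples$group
    smd <- abs(apply(la, 2, function(x)
      (mean(x[grp == "case"]) - mean(x[grp == "control"])) /
        sqrt((var(x[grp == "case"]) + var(x[grp == "control"])) / 2)))
    bio <- st$truth$biomarker_indices
    thr <- quantile(smd[-bio], 0.95)
    if (all(smd[bio] > thr)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("null configuration plants nothing", {
  st <- generate_study(small_cfg(seed = 5, effect_size = 0,
                                 pcor_strength = 0))
  la <- log(st$set1$abund)
  grp <- st$set1$samples$group
  p <- apply(la, 2, function(x)
    t.test(x[grp == "case"], x[grp == "control"])$p.value)
  # planted indices behave like any other feature under the null
  expect_gt(min(p[st$truth$biomarker_indices]), 0.001)
})

test_that("infeasible and invalid configurations fail fast", {
  expect_error(sim_config(n_biomarkers = 50, n_network = 60,
                          n_identified = 70, n_features = 60),
               "n_identified")
  expect_error(sim_config(n_biomarkers = 9, n_network = 5), "n_biomarkers")
  expect_error(sim_config(pcor_strength = 1), "pcor_strength")
  expect_error(sim_config(risk_allele_freqs = c(0.01, 0.3)), "risk_allele")
})

test_that("feature tables and genotypes round-trip through TSV", {
  st <- generate_study(small_cfg(seed = 11))
  d <- withr::local_tempdir()
  write_feature_table(st$set1, file.path(d, "a.tsv"), file.path(d, "f.tsv"))
  back <- read_feature_table(file.path(d, "a.tsv"), file.path(d, "f.tsv"))
  expect_equal(back$abund, st$set1$abund, tolerance = 1e-9)
  expect_equal(back$qc_detection, st$set1$qc_detection, tolerance = 1e-12)
  expect_identical(back$samples$group, st$set1$samples$group)

  write_genotypes(st$genotypes, file.path(d, "g.tsv"))
  gback <- read_genotypes(file.path(d, "g.tsv"))
  expect_identical(unname(gback$geno), unname(st$genotypes$geno))
})
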
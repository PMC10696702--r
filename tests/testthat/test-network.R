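test_that("partial correlations agree with closed forms and regression residuals", {
  # p = 2: nothing to condition on, pcor equals Pearson correlation
  set.seed(121)
  X2 <- matrix(rnorm(100), 50, 2)
  expect_equal(partial_correlations(X2, shrinkage = 0)[1, 2], cor(X2)[1, 2],
               tolerance = 1e-10)

  # trivariate closed form: all marginal correlations 0.5 gives pcor = 1/3
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(pcor_from_precision(solve(R))[1, 2], 1 / 3, tolerance = 1e-10)

  # regression-residual oracle on every pair
  set.seed(122)
  X <- matrix(rnorm(50 * 6), 50, 6) %*% matrix(rnorm(36, sd = 0.5), 6, 6)
  pc <- partial_correlations(X, shrinkage = 0)
  for (i in 1:5) for (j in (i + 1):6) {
    ri <- lm.fit(cbind(1, X[, -c(i, j)]), X[, i])$residuals
    rj <- lm.fit(cbind(1, X[, -c(i, j)]), X[, j])$residuals
    expect_equal(pc[i, j], cor(ri, rj), tolerance = 1e-8)
  }

  # closed-form check against sample marginal correlations at p = 3
  r <- cor(X[, 1:3])
  expect_equal(partial_correlations(X[, 1:3], shrinkage = 0)[1, 2],
               (r[1, 2] - r[1, 3] * r[2, 3]) /
                 sqrt((1 - r[1, 3]^2) * (1 - r[2, 3]^2)), tolerance = 1e-8)

  expect_error(partial_correlations(matrix(rnorm(8), 4, 2)[, c(1, 1, 2)],
                                    shrinkage = 0), "singular")
})

test_that("Fisher-z edge tests give the reported significance scale", {
  pc <- diag(23)
  pc[1, 2] <- pc[2, 1] <- 0.442
  ed <- edge_tests(pc, n = 132)
  top <- ed[1, ]
  expect_equal(top$r, 0.442)
  # df = n - (p - 2) - 3 = 108, so z*sqrt(df) ~ 4.9: well below 0.001
  expect_lt(top$p, 0.001)
  # zero pcor has p = 1
  expect_equal(ed$p[ed$r == 0][1], 1)
  expect_error(edge_tests(diag(30), n = 25), "degrees of freedom")
})

test_that("null data produce few significant edges", {
  set.seed(131)
  frac <- vapply(1:20, function(r) {
    X <- matrix(rnorm(100 * 12), 100, 12)
    ed <- edge_tests(partial_correlations(X, shrinkage = 0), n = 100)
    mean(ed$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  # path A-B-C
  out <- betweenness_centrality(data.frame(i = c("A", "B"), j = c("B", "C")),
                                nodes = c("A", "B", "C"))
  expect_equal(out$betweenness, c(0, 1, 0))
  expect_identical(out$displayed, c(FALSE, TRUE, FALSE))

  # star with k leaves: center = choose(k, 2)
  k <- 6
  star <- data.frame(i = "hub", j = paste0("leaf", 1:k))
  outs <- betweenness_centrality(star, nodes = c("hub", paste0("leaf", 1:k)))
  expect_equal(outs$betweenness[outs$node == "hub"], choose(k, 2))
  expect_true(all(outs$betweenness[outs$node != "hub"] == 0))

  # random graphs up to 8 nodes vs the brute-force oracle
  set.seed(141)
  for (r in 1:25) {
    p <- sample(4:8, 1)
    adj <- matrix(0L, p, p)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    adj[pairs[on, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    nodes <- paste0("n", seq_len(p))
    eidx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    edges <- data.frame(i = nodes[eidx[, 1]], j = nodes[eidx[, 2]])
    got <- betweenness_centrality(edges, nodes)$betweenness
    expect_equal(got, brute_force_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("node effect z-scores flag exactly the planted pattern", {
  # identical groups: z = 0, q = 1
  ab <- exp(matrix(rnorm(40), 20, 2))
  abi <- rbind(ab, ab)
  z0 <- node_effect_z(abi, rep(c("case", "control"), each = 20))
  expect_equal(z0$z, c(0, 0), ignore_attr = TRUE)
  expect_equal(z0$q, c(1, 1))

  # 3-pooled-SD shift at n = 66 + 66: |z| > 5 deterministically
  set.seed(151)
  x <- matrix(rnorm(132), ncol = 1)
  x[1:66] <- x[1:66] + 3
  z3 <- node_effect_z(exp(x), rep(c("case", "control"), each = 66))
  expect_gt(abs(z3$z), 5)

  # planted 17-of-23 pattern at effect 1.0: every planted node is flagged
  # in nearly all replicates, and false flags on the 6 null nodes stay at
  # the BH-FDR-controlled rate (expected ~0.2 per replicate)
  full_power <- 0L; false_flags <- 0L
  for (r in 1:20) {
    set.seed(500 + r)
    la <- matrix(rnorm(132 * 23), 132, 23)
    grp <- rep(c("case", "control"), each = 66)
    la[grp == "case", 1:17] <- la[grp == "case", 1:17] + 1.0
    nz <- node_effect_z(exp(la), grp)
    flagged <- which(nz$significant)
    if (all(1:17 %in% flagged)) full_power <- full_power + 1L
    false_flags <- false_flags + length(setdiff(flagged, 1:17))
  }
  expect_gte(full_power, 18L)
  expect_lte(false_flags, 10L)
})

test_that("edge recovery on planted truth reaches F1 >= 0.9", {
  om <- make_precision_matrix(23, density = 0.1, strength = 0.4, seed = 161)
  truth_edges <- attr(om, "edges")
  set.seed(162)
  X <- MASS::mvrnorm(500, rep(0, 23), solve(om))
  ed <- edge_tests(partial_correlations(X, shrinkage = 0), n = 500)
  got <- ed[ed$significant, c("i", "j")]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  truth_k <- key(truth_edges[, 1], truth_edges[, 2])
  got_k <- key(as.integer(got$i), as.integer(got$j))
  tp <- length(intersect(got_k, truth_k))
  prec <- tp / length(got_k); rec <- tp / length(truth_k)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.9)
})

test_that("build_network assembles nodes, edges and centrality coherently", {
  st <- generate_study(small_cfg(seed = 171, effect_size = 1.0))
  kept <- qc_filter(st$set1)
  sub <- subset_features(kept, match(sprintf("F%04d", 1:8),
                                     kept$features$feature_id))
  net <- build_network(sub)
  expect_s3_class(net, "network_model")
  expect_identical(nrow(net$nodes), 8L)
  expect_true(all(abs(net$pcor[upper.tri(net$pcor)]) <= 1))
  expect_equal(unname(diag(net$pcor)), rep(1, 8))
  expect_true(all(net$nodes$betweenness >= 0))
  # significant flag consistent with q threshold
  expect_identical(net$nodes$significant, net$nodes$q < 0.05)

  d <- withr::local_tempdir()
  write_network(net, file.path(d, "g.graphml"), file.path(d, "e.tsv"),
                file.path(d, "n.tsv"))
  expect_true(all(file.exists(file.path(d, c("g.graphml", "e.tsv", "n.tsv")))))
})
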
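# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct Newton solves,
# and small-n Monte Carlo.

# Shortest-path betweenness by exhaustive path enumeration (BFS shortest
# path counting done naively per pair, accumulating interior nodes).
brute_force_betweenness <- function(adj) {
  p <- nrow(adj)
  bc <- numeric(p)
  # all shortest paths between s and t by depth-limited DFS
  all_shortest_paths <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, p); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in which(adj[v, ] == 1))
        if (dist[u] > dist[v] + 1) { dist[u] <- dist[v] + 1; queue <- c(queue, u) }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (u in which(adj[v, ] == 1))
        if (dist[u] == dist[v] + 1) walk(c(path, u))
    }
    walk(s)
    paths
  }
  for (s in seq_len(p - 1)) for (t in seq(s + 1, p)) {
    paths <- all_shortest_paths(s, t)
    if (length(paths) == 0) next
    for (pa in paths) {
      interior <- setdiff(pa, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(paths)
    }
  }
  bc
}

# Logistic regression by direct Newton-Raphson on the log-likelihood.
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- crossprod(X, y - mu)
    hess <- crossprod(X * w, X)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

# AUC as the exact pairwise concordance count (ties score 1/2).
pairwise_auc <- function(scores, y) {
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Hypergeometric upper tail by explicit enumeration of all draws.
enum_hyper_p <- function(hits, class_size, bg_size, draw) {
  # P(X >= hits) by summing choose terms
  ks <- hits:min(class_size, draw)
  sum(choose(class_size, ks) * choose(bg_size - class_size, draw - ks)) /
    choose(bg_size, draw)
}

# Monte Carlo HWE p-value: shuffle the 2n alleles into pairs and compare
# heterozygote-count probabilities empirically.
mc_hwe_p <- function(n_hom_minor, n_het, n_hom_major, n_sim = 2e5, seed = 42) {
  n <- n_hom_minor + n_het + n_hom_major
  n_minor <- min(2 * n_hom_minor + n_het, 2 * n_hom_major + n_het)
  alleles <- c(rep(1, n_minor), rep(0, 2 * n - n_minor))
  set.seed(seed)
  hets <- replicate(n_sim, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  freq <- table(hets) / n_sim
  p_obs <- freq[as.character(n_het)]
  if (is.na(p_obs)) p_obs <- 0
  sum(freq[freq <= as.numeric(p_obs) + 1e-9])
}

# Small, fast simulation config used by many tests.
small_cfg <- function(seed = 1, ...) {
  args <- list(n_cases_set1 = 20, n_controls_set1 = 20,
               n_cases_set2 = 18, n_controls_set2 = 18,
               n_features = 80, n_identified = 40, n_network = 8,
               n_biomarkers = 5, effect_size = 1.5,
               precision_matrix_density = 0.1, pcor_strength = 0.3,
               n_snps = 30, n_risk_snps = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Random scaled matrix + labels for invariant sweeps.
random_problem <- function(seed, n = 24, p = 12, effect = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "b", seq_len(3)] <- X[y == "b", seq_len(3)] + effect
  scale(X, scale = FALSE)
}
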
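# Gaussian graphical model machinery: partial correlations from the
# (optionally shrunk) inverse covariance, Fisher-z edge tests with BH-FDR,
# betweenness centrality of the significant-edge graph, and per-metabolite
# effect z-scores between groups.

#' Partial correlation matrix of a data matrix
#'
#' `pcor(i, j) = -omega_ij / sqrt(omega_ii * omega_jj)` from the inverse of
#' the (optionally regularised) covariance: the correlation of each pair
#' conditioned on all remaining variables. With `shrinkage = "auto"` an
#' analytic correlation-shrinkage intensity toward the diagonal target
#' (Ledoit-Wolf / Schafer-Strimmer style) is used when `p / n > 0.2`, and no
#' shrinkage otherwise.
#'
#' @param X numeric matrix (samples x variables), `n > 3`, `p >= 2`.
#' @param shrinkage `"auto"`, or a numeric intensity in `[0, 1)`
#'   (0 = unregularised sample covariance).
#' @return partial correlation matrix with unit diagonal and a
#'   `shrinkage` attribute giving the intensity used.
#' @export
partial_correlations <- function(X, shrinkage = "auto") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= 3) stop("need n > 3 samples")
  if (p < 2) stop("need at least 2 variables")
  lambda <- if (identical(shrinkage, "auto")) {
    if (p / n > 0.2) shrinkage_intensity(X) else 0
  } else as.numeric(shrinkage)
  r <- cor(X)
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- tryCatch(solve(rs), error = function(e)
    stop("covariance is singular; set shrinkage > 0 (or \"auto\")"))
  if (lambda == 0 && kappa(rs) > 1e12)
    stop("covariance is near-singular; set shrinkage > 0 (or \"auto\")")
  pc <- pcor_from_precision(omega)
  dimnames(pc) <- list(colnames(X), colnames(X))
  attr(pc, "shrinkage") <- lambda
  pc
}

# Analytic shrinkage intensity for the off-diagonal correlations:
# lambda* = sum var-hat(r_ij) / sum r_ij^2 (clamped to [0, 1)).
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  Xs <- scale(X)
  w_mean <- crossprod(Xs) / n                       # ~ r_ij
  # var of the pairwise products around their mean, standard unbiased form
  v <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) {
    wk <- tcrossprod(Xs[i, ])
    v <- v + (wk - w_mean)^2
  }
  v <- v * n / ((n - 1)^3)
  r <- w_mean * n / (n - 1)
  off <- upper.tri(r)
  lam <- sum(v[off]) / sum(r[off]^2)
  min(max(lam, 0), 0.9999)
}

#' Edge significance tests for a partial correlation matrix
#'
#' Fisher z-transform of each partial correlation with standard error
#' `1 / sqrt(n - (p - 2) - 3)` (the degrees of freedom account for the
#' `p - 2` conditioning variables), two-sided normal p-values and
#' Benjamini-Hochberg FDR across all pairs.
#'
#' @param pcor partial correlation matrix.
#' @param n number of samples the matrix was estimated from.
#' @param q_threshold FDR threshold defining the significant edge set.
#' @return data.frame of all pairs (`i`, `j`, `r`, `p`, `q`, `significant`),
#'   ordered by p.
#' @export
edge_tests <- function(pcor, n, q_threshold = 0.05) {
  p <- ncol(pcor)
  df <- n - (p - 2) - 3
  if (df < 1)
    stop("insufficient degrees of freedom for the Fisher transform: ",
         "n - (p - 2) - 3 = ", df)
  pairs <- which(upper.tri(pcor), arr.ind = TRUE)
  r <- pcor[pairs]
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  pv <- 2 * pnorm(-abs(z) * sqrt(df))
  ids <- colnames(pcor) %||% as.character(seq_len(p))
  out <- data.frame(i = ids[pairs[, 1]], j = ids[pairs[, 2]],
                    r = r, p = pv, q = p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < q_threshold
  out[order(out$p), ]
}

#' Betweenness centrality of an edge list
#'
#' Unweighted, non-normalised shortest-path betweenness on the simple
#' undirected graph formed by the given edges (isolated nodes score 0).
#' Nodes below `display_cutoff` are flagged (`displayed = FALSE`), not
#' removed -- the cutoff is a display threshold.
#'
#' @param edges data.frame with columns `i`, `j` (node names).
#' @param nodes character vector of all node names.
#' @param display_cutoff centrality display threshold (default 0.5).
#' @return data.frame `node`, `betweenness`, `displayed`.
#' @export
betweenness_centrality <- function(edges, nodes, display_cutoff = 0.5) {
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.frame(node = nodes, betweenness = as.numeric(b[nodes]),
             displayed = as.numeric(b[nodes]) >= display_cutoff,
             stringsAsFactors = FALSE)
}

#' Per-metabolite effect z-scores between groups
#'
#' For each metabolite, a Welch t-test of log abundance between the two
#' groups; the two-sided p-value is mapped through the standard normal
#' quantile to an effect z-score (signed by the direction of the difference),
#' with Benjamini-Hochberg FDR across metabolites. This gives a common
#' normal-scale effect measure across metabolites with unequal variances.
#'
#' @param abund raw-scale abundance matrix (samples x metabolites).
#' @param groups two-level grouping aligned with rows.
#' @param q_threshold significance threshold on the FDR q.
#' @return data.frame `node`, `z`, `p`, `q`, `significant`; metabolites with
#'   zero variance in both groups get `NA` z and a `significant` of `NA`.
#' @export
node_effect_z <- function(abund, groups, q_threshold = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (any(table(groups) < 2)) stop("both groups need >= 2 samples")
  la <- log(impute_half_min(as.matrix(abund)))
  res <- apply(la, 2, function(x) {
    x1 <- x[groups == levels(groups)[2]]  # e.g. case
    x0 <- x[groups == levels(groups)[1]]
    if (var(x1) == 0 && var(x0) == 0) return(c(NA_real_, NA_real_))
    tt <- t.test(x1, x0)
    c(sign(tt$statistic) * qnorm(1 - tt$p.value / 2), tt$p.value)
  })
  z <- res[1, ]; pv <- res[2, ]
  q <- p.adjust(pv, "BH")
  data.frame(node = colnames(la) %||% as.character(seq_len(ncol(la))),
             z = z, p = pv, q = q, significant = q < q_threshold,
             stringsAsFactors = FALSE)
}

#' Build a Gaussian graphical model network
#'
#' Convenience wrapper: estimates partial correlations on log + Pareto scaled
#' abundances, tests edges, computes betweenness on the significant-edge
#' graph, and overlays per-node effect z-scores between the groups.
#'
#' @param table a [feature_table()] restricted to the metabolites of
#'   interest (typically the replicated selection).
#' @param groups two-level grouping (defaults to the table's `group`).
#' @param shrinkage passed to [partial_correlations()].
#' @param edge_q,node_q FDR thresholds for edges and node effects.
#' @param display_cutoff betweenness display threshold.
#' @return object of class `network_model`: `nodes` (data.frame with
#'   betweenness, z, q, significance), `pcor`, `edges` (all pairs with
#'   r/p/q), `n`, `shrinkage`.
#' @export
build_network <- function(table, groups = NULL, shrinkage = "auto",
                          edge_q = 0.05, node_q = 0.05,
                          display_cutoff = 0.5) {
  groups <- groups %||% table$samples$group
  Xs <- log_pareto(table)
  pc <- partial_correlations(Xs, shrinkage = shrinkage)
  ed <- edge_tests(pc, n = nrow(Xs), q_threshold = edge_q)
  bt <- betweenness_centrality(ed[ed$significant, , drop = FALSE],
                               nodes = colnames(pc),
                               display_cutoff = display_cutoff)
  nz <- node_effect_z(table$abund, groups, q_threshold = node_q)
  nodes <- merge(bt, nz, by = "node", sort = FALSE)
  structure(list(nodes = nodes, pcor = pc, edges = ed, n = nrow(Xs),
                 shrinkage = attr(pc, "shrinkage")),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", nrow(x$nodes), " nodes, ",
      sum(x$edges$significant), " significant edges (q < 0.05), ",
      sum(x$nodes$significant, na.rm = TRUE),
      " nodes significant in z-score\n", sep = "")
  invisible(x)
}

#' Export a network as GraphML and TSV
#'
#' @param model a `network_model`.
#' @param graphml_path,edges_path,nodes_path output paths (any may be
#'   `NULL` to skip).
#' @export
write_network <- function(model, graphml_path = NULL, edges_path = NULL,
                          nodes_path = NULL) {
  sig <- model$edges[model$edges$significant, , drop = FALSE]
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      sig[, c("i", "j", "r", "p", "q")], directed = FALSE,
      vertices = model$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path))
    write.table(model$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(nodes_path))
    write.table(model$nodes, nodes_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(model)
}
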
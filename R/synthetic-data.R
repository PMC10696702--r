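#' Simulation configuration for a two-set case-control study
#'
#' Defaults emulate the study design this pipeline targets: two independent
#' male case-control sets of 35+35 and 31+31 subjects, 2610 detected features
#' of which 250 are identified metabolites, a 23-metabolite dependency network
#' in which 17 metabolites carry a case/control shift, and a genotyped SNP
#' panel driving disease risk through a sparse set of causal variants.
#'
#' Abundances are log-normal: a latent Gaussian on the log scale (so that the
#' preprocessing log transform recovers the Gaussian assumption of the
#' graphical model) with the network block's covariance equal to the inverse
#' of the planted precision matrix. The standardized effect is applied on the
#' log scale; with the default log-SD of 0.5 an effect of 0.75 corresponds to
#' case/control fold changes around 1.45, the scale reported for replicated
#' serum biomarkers in this setting.
#'
#' @param n_cases_set1,n_controls_set1,n_cases_set2,n_controls_set2 group
#'   sizes per set.
#' @param n_features total detected features.
#' @param n_identified number of features that are identified metabolites
#'   (always detected in QC injections); the first `n_identified` features.
#' @param n_network size of the correlated metabolite block carrying the
#'   planted precision structure; the first `n_network` features.
#' @param n_biomarkers number of network metabolites carrying a case/control
#'   mean shift; the first `n_biomarkers` features. Must be
#'   `<= n_network <= n_identified <= n_features`.
#' @param effect_size standardized mean shift (log scale, in SD units) added
#'   to cases on biomarker features, in both sets.
#' @param precision_matrix_density fraction of off-diagonal entries of the
#'   network precision matrix that are nonzero, in `[0, 1)`.
#' @param pcor_strength magnitude of planted partial correlations, in `[0, 1)`.
#' @param n_snps,n_risk_snps genotyped and causal SNP counts.
#' @param risk_allele_freqs length-2 range (or per-SNP vector) of risk allele
#'   frequencies, inside `(0.05, 0.95)`.
#' @param snp_effect_logodds per-causal-SNP log odds ratio.
#' @param qc_detect_prob_background detection probability of a background
#'   (non-identified) feature in one QC injection.
#' @param n_qc_injections number of QC injections used for the detection
#'   fraction (default 13: one per ten study samples).
#' @param n_qc_replicates intra-assay QC replicate injections (default 7).
#' @param sdlog log-scale SD of abundances (biological variation).
#' @param sdlog_qc log-scale SD of repeated QC injections (analytical
#'   variation; 0.1 gives ~10% RSD).
#' @param seed integer seed; the same seed reproduces the study byte for byte.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases_set1 = 35, n_controls_set1 = 35,
                       n_cases_set2 = 31, n_controls_set2 = 31,
                       n_features = 2610, n_identified = 250,
                       n_network = 23, n_biomarkers = 17,
                       effect_size = 0.75,
                       precision_matrix_density = 0.1, pcor_strength = 0.4,
                       n_snps = 500, n_risk_snps = 10,
                       risk_allele_freqs = c(0.1, 0.4),
                       snp_effect_logodds = 0.8,
                       qc_detect_prob_background = 0.5,
                       n_qc_injections = 13, n_qc_replicates = 7,
                       sdlog = 0.5, sdlog_qc = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_biomarkers > n_network)
      stop("n_biomarkers must be <= n_network")
    if (n_network > n_identified)
      stop("n_network must be <= n_identified")
    if (n_identified > n_features)
      stop("n_identified must be <= n_features (n_biomarkers <= n_features)")
    if (n_risk_snps > n_snps) stop("n_risk_snps must be <= n_snps")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (pcor_strength < 0 || pcor_strength >= 1)
      stop("pcor_strength must be in [0, 1)")
    if (precision_matrix_density < 0 || precision_matrix_density >= 1)
      stop("precision_matrix_density must be in [0, 1)")
    if (any(risk_allele_freqs <= 0.05) || any(risk_allele_freqs >= 0.95))
      stop("risk_allele_freqs must lie in (0.05, 0.95)")
  })
  invisible(cfg)
}

#' Build a sparse symmetric positive-definite precision matrix
#'
#' Plants a random undirected graph at the requested edge density and sets the
#' corresponding off-diagonal precision entries so that the implied partial
#' correlation of each edge, `-omega_ij / sqrt(omega_ii * omega_jj)`, has
#' magnitude `strength` (random sign). Diagonal dominance is enforced: if any
#' row's absolute off-diagonal sum reaches 1, all off-diagonal entries are
#' scaled down so positive definiteness is guaranteed (edge partial
#' correlations then shrink below `strength`; they never change sign).
#'
#' @param p matrix dimension (`>= 2`).
#' @param density fraction of the `p*(p-1)/2` off-diagonal pairs that are
#'   edges, in `[0, 1)`.
#' @param strength magnitude of the implied partial correlation per edge,
#'   in `[0, 1)`.
#' @param seed integer seed (the edge set and signs are random).
#' @return A `p x p` precision matrix with unit diagonal and an
#'   `edges` attribute (two-column index matrix, `i < j`).
#' @export
make_precision_matrix <- function(p, density, strength, seed = 1L) {
  stopifnot(p >= 2, density >= 0, density < 1, strength >= 0, strength < 1)
  with_seed(seed, {
    omega <- diag(p)
    pairs <- which(upper.tri(omega), arr.ind = TRUE)
    n_edges <- floor(density * nrow(pairs))
    edges <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    if (n_edges > 0) {
      signs <- sample(c(-1, 1), n_edges, replace = TRUE)
      # pcor(i,j) = -omega_ij with unit diagonal
      omega[edges] <- -signs * strength
      omega[edges[, 2:1, drop = FALSE]] <- omega[edges]
      # per-edge diagonal-dominance scaling: only edges touching a row whose
      # absolute off-diagonal sum reaches 1 are shrunk, so low-degree nodes
      # keep the full planted strength
      row_off <- rowSums(abs(omega)) - 1
      if (max(row_off) >= 0.95) {
        for (k in seq_len(n_edges)) {
          i <- edges[k, 1]; j <- edges[k, 2]
          s <- min(1, 0.95 / max(row_off[i], row_off[j]))
          omega[i, j] <- omega[i, j] * s
          omega[j, i] <- omega[i, j]
        }
      }
    }
    if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("internal error: constructed precision matrix not positive definite")
    colnames(edges) <- c("i", "j")
    attr(omega, "edges") <- edges[order(edges[, 1], edges[, 2]), ,
                                  drop = FALSE]
    omega
  })
}

#' Implied partial correlations of a precision matrix
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return matrix of partial correlations, unit diagonal.
#' @export
pcor_from_precision <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  pc
}

# Ground truth of a generated study.
generate_truth <- function(config) {
  seed_t <- substream_seed(config$seed, 1L)
  omega <- make_precision_matrix(config$n_network,
                                 config$precision_matrix_density,
                                 config$pcor_strength, seed = seed_t)
  with_seed(substream_seed(config$seed, 2L), {
    f <- config$risk_allele_freqs
    freqs <- if (length(f) == config$n_snps) f
             else runif(config$n_snps, min(f), max(f))
    risk_idx <- sort(sample.int(config$n_snps, config$n_risk_snps))
    weights <- rep(0, config$n_snps)
    weights[risk_idx] <- config$snp_effect_logodds
    structure(list(biomarker_indices = seq_len(config$n_biomarkers),
                   true_precision = omega,
                   true_edges = attr(omega, "edges"),
                   risk_snp_indices = risk_idx,
                   true_snp_weights = weights,
                   risk_allele_freqs = freqs),
              class = "synthetic_truth")
  })
}

# Draw subjects with genotypes and disease status from the logistic model,
# until the exact case and control quotas are met (stratified sampling).
draw_subjects <- function(n_cases, n_controls, truth, config) {
  n_snps <- config$n_snps
  alpha <- -sum(truth$true_snp_weights * 2 * truth$risk_allele_freqs)
  got_case <- got_ctrl <- 0L
  geno_keep <- matrix(NA_integer_, n_cases + n_controls, n_snps)
  status_keep <- integer(n_cases + n_controls)
  lp_keep <- numeric(n_cases + n_controls)
  attempts <- 0L
  max_attempts <- 400L * (n_cases + n_controls)
  batch <- max(64L, 2L * (n_cases + n_controls))
  while (got_case < n_cases || got_ctrl < n_controls) {
    if (attempts >= max_attempts)
      stop("infeasible config: could not reach requested case/control ",
           "counts given the SNP disease model")
    g <- matrix(rbinom(batch * n_snps, 2L,
                       rep(truth$risk_allele_freqs, each = batch)),
                batch, n_snps)
    lp <- alpha + as.vector(g %*% truth$true_snp_weights)
    status <- rbinom(batch, 1L, plogis(lp))
    for (b in seq_len(batch)) {
      if (status[b] == 1L && got_case < n_cases) {
        got_case <- got_case + 1L
        k <- got_case
      } else if (status[b] == 0L && got_ctrl < n_controls) {
        got_ctrl <- got_ctrl + 1L
        k <- n_cases + got_ctrl
      } else next
      geno_keep[k, ] <- g[b, ]
      status_keep[k] <- status[b]
      lp_keep[k] <- lp[b]
      if (got_case == n_cases && got_ctrl == n_controls) break
    }
    attempts <- attempts + batch
  }
  list(geno = geno_keep, status = status_keep, lp = lp_keep)
}

# Feature annotation frame shared by both sets.
make_annotation <- function(config) {
  p <- config$n_features
  classes <- c("Organic acids and derivatives", "Organoheterocyclic compounds",
               "Benzenoids", "Organic oxygen compounds", "Fatty acyls",
               "Phenylpropanoids and polyketides",
               "Organic nitrogen compounds", "Lipids and lipid-like molecules")
  data.frame(
    feature_id = sprintf("F%04d", seq_len(p)),
    hmdb_like_id = ifelse(seq_len(p) <= config$n_identified,
                          sprintf("SYN%07d", seq_len(p)), NA_character_),
    mz = round(runif(p, 80, 700), 3),
    formula = sprintf("C%dH%dN%dO%d", sample(2:30, p, TRUE),
                      sample(4:60, p, TRUE), sample(0:4, p, TRUE),
                      sample(0:8, p, TRUE)),
    super_class = sample(classes, p, replace = TRUE),
    identified = seq_len(p) <= config$n_identified,
    stringsAsFactors = FALSE
  )
}

# One study set's feature table given subject status and shared parameters.
make_set_table <- function(set_name, status, age, draw_date, config, truth,
                           annotation, mu, qc_detection, qc_replicates) {
  n <- length(status)
  p <- config$n_features
  k <- config$n_network
  sigma <- solve(truth$true_precision)
  z <- matrix(rnorm(n * p), n, p)
  lat <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
  z[, seq_len(k)] <- sweep(lat, 2, sqrt(diag(sigma)), "/")
  bio <- truth$biomarker_indices
  z[status == 1L, bio] <- z[status == 1L, bio, drop = FALSE] +
    config$effect_size
  log_abund <- sweep(z * config$sdlog, 2, mu, "+")
  abund <- exp(log_abund)
  samples <- data.frame(
    sample_id = sprintf("%s_S%03d", set_name, seq_len(n)),
    set = set_name,
    group = ifelse(status == 1L, "case", "control"),
    age = age, draw_date = draw_date, stringsAsFactors = FALSE)
  feature_table(abund, samples, annotation,
                qc_detection = qc_detection, qc_replicates = qc_replicates)
}

#' Generate a complete synthetic two-set study
#'
#' Produces two case-control feature tables, a genotype panel covering all
#' subjects, and the planted ground truth. Case status is generated from a
#' logistic disease model on the causal SNP allele counts, then subjects are
#' sampled stratified to hit the exact group sizes of each set. QC-injection
#' detection flags are simulated per feature (identified metabolites always
#' detected; background features detected with
#' `qc_detect_prob_background`).
#'
#' @param config a [sim_config()].
#' @param truth optionally, a ground truth from a previous call with the same
#'   structural parameters; used to simulate additional cohorts (e.g. a
#'   genotype reference cohort) from the same planted model.
#' @return list with elements `set1`, `set2` ([feature_table()]s),
#'   `genotypes` ([genotype_panel()]), `truth` (`synthetic_truth`).
#' @export
generate_study <- function(config, truth = NULL) {
  validate_sim_config(config)
  if (is.null(truth)) truth <- generate_truth(config)

  annotation <- with_seed(substream_seed(config$seed, 3L),
                          make_annotation(config))

  # QC detection fractions and intra-assay replicates (shared acquisition)
  qc <- with_seed(substream_seed(config$seed, 4L), {
    detect_prob <- ifelse(annotation$identified, 1.0,
                          config$qc_detect_prob_background)
    det <- rbinom(config$n_features, config$n_qc_injections, detect_prob) /
      config$n_qc_injections
    mu <- runif(config$n_features, log(1e4), log(1e7))
    reps <- exp(sweep(matrix(rnorm(config$n_qc_replicates *
                                     config$n_features, sd = config$sdlog_qc),
                             config$n_qc_replicates, config$n_features),
                      2, mu, "+"))
    list(detection = det, replicates = reps, mu = mu)
  })

  sets <- list(
    set1 = c(config$n_cases_set1, config$n_controls_set1),
    set2 = c(config$n_cases_set2, config$n_controls_set2))
  tables <- list()
  geno_all <- NULL
  samp_all <- NULL
  for (s in seq_along(sets)) {
    nm <- names(sets)[s]
    res <- with_seed(substream_seed(config$seed, 10L + s), {
      subj <- draw_subjects(sets[[s]][1], sets[[s]][2], truth, config)
      n <- length(subj$status)
      age <- pmin(69, pmax(35, round(rnorm(n, 52 + 2 * subj$status, 7), 1)))
      draw_date <- as.character(as.Date("2004-01-01") +
                                  sample.int(3650L, n, replace = TRUE))
      tab <- make_set_table(nm, subj$status, age, draw_date, config, truth,
                            annotation, qc$mu, qc$detection, qc$replicates)
      list(tab = tab, geno = subj$geno)
    })
    tables[[nm]] <- res$tab
    geno_all <- rbind(geno_all, res$geno)
    samp_all <- rbind(samp_all, res$tab$samples[c("sample_id", "set",
                                                  "group", "age")])
  }

  # sporadic genotype missingness
  geno_all <- with_seed(substream_seed(config$seed, 20L), {
    miss_rate <- runif(config$n_snps, 0, 0.02)
    drop <- matrix(rbinom(length(geno_all), 1L,
                          rep(miss_rate, each = nrow(geno_all))) == 1L,
                   nrow(geno_all), config$n_snps)
    geno_all[drop] <- NA_integer_
    geno_all
  })
  rownames(geno_all) <- samp_all$sample_id
  colnames(geno_all) <- sprintf("rs%06d", seq_len(config$n_snps))
  panel <- genotype_panel(geno_all, samples = samp_all)

  list(set1 = tables$set1, set2 = tables$set2, genotypes = panel,
       truth = truth)
}

#' Write the planted ground truth as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(biomarker_indices = truth$biomarker_indices,
         true_precision = truth$true_precision,
         true_edges = truth$true_edges,
         risk_snp_indices = truth$risk_snp_indices,
         true_snp_weights = truth$true_snp_weights,
         risk_allele_freqs = truth$risk_allele_freqs),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
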
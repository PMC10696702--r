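#' Default pipeline configuration
#'
#' Nested list of stage parameters; `sim` holds the [sim_config()]
#' arguments. Override any entry, or supply a YAML/JSON file with the same
#' structure to [run_pipeline()].
#'
#' @param seed global seed; expanded to per-stage substreams.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(seed = as.integer(seed)),
    preprocess = list(min_detect = 0.8, rsd_threshold = 15),
    oplsda = list(folds = 7, n_perm = 100, max_orth = 5),
    selection = list(vip_threshold = 1.0),
    network = list(edge_q = 0.05, node_q = 0.05, shrinkage = "auto",
                   display_cutoff = 0.5),
    grs = list(n_reference = 500, p_threshold = 5e-5),
    predict = list(n_markers = 5)
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  base <- default_config(config$seed %||% 1L)
  for (sec in names(config)) {
    if (is.list(config[[sec]]))
      for (k in names(config[[sec]])) base[[sec]][[k]] <- config[[sec]][[k]]
    else base[[sec]] <- config[[sec]]
  }
  base
}

#' Simulate a genotype reference cohort from an existing ground truth
#'
#' Draws additional subjects (genotypes, age, case status) from the same
#' planted disease model, e.g. to estimate GRS weights on an independent
#' cohort before scoring the study subjects.
#'
#' @param config a [sim_config()]; @param truth its `synthetic_truth`.
#' @param n_cases,n_controls cohort sizes; @param seed integer seed.
#' @return list with `panel` ([genotype_panel()]), `status`, `age`.
#' @export
sim_reference_cohort <- function(config, truth, n_cases = 250,
                                 n_controls = 250, seed = 1L) {
  with_seed(seed, {
    subj <- draw_subjects(n_cases, n_controls, truth, config)
    n <- length(subj$status)
    age <- pmin(69, pmax(35, round(rnorm(n, 52 + 2 * subj$status, 7), 1)))
    geno <- subj$geno
    rownames(geno) <- sprintf("REF_S%04d", seq_len(n))
    colnames(geno) <- sprintf("rs%06d", seq_len(config$n_snps))
    panel <- genotype_panel(geno, samples = data.frame(
      sample_id = rownames(geno),
      group = ifelse(subj$status == 1L, "case", "control"),
      age = age, stringsAsFactors = FALSE))
    list(panel = panel, status = subj$status, age = age, lp = subj$lp)
  })
}

#' Run the full discovery pipeline on a synthetic study
#'
#' Executes, in order: simulation, propensity matching, QC filtering and
#' scaling, per-set OPLS-DA with permutation testing, replicated VIP
#' selection with super-class enrichment, Gaussian graphical model network
#' (case/control and GRS-high/low among cases), reference-cohort GWAS and
#' GRS construction, and logistic ROC prediction models (markers, markers
#' without the top marker, markers + GRS). All stage artifacts are written
#' as TSV/JSON/GraphML under `out_dir` together with a run manifest (config
#' snapshot, per-stage seeds, md5 checksums, package version). Any stage
#' failure aborts with the stage name; artifacts of completed stages are
#' preserved.
#'
#' @param config a configuration list as from [default_config()], or a path
#'   to a YAML/JSON file of overrides.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pathof <- function(f) file.path(out_dir, f)

  res$study <- stage("simulate", {
    sim_args <- cfg$sim
    study <- do.call(sim_config, sim_args)
    study <- generate_study(study)
    write_feature_table(study$set1, pathof("set1_abund.tsv"),
                        pathof("set1_annot.tsv"))
    write_feature_table(study$set2, pathof("set2_abund.tsv"),
                        pathof("set2_annot.tsv"))
    write_genotypes(study$genotypes, pathof("genotypes.tsv"))
    write_truth(study$truth, pathof("truth.json"))
    study
  })

  res$matching <- stage("match", {
    out <- lapply(list(res$study$set1, res$study$set2), function(tab) {
      s <- tab$samples
      s$draw_time <- as.numeric(as.Date(s$draw_date))
      propensity_match(s[s$group == "case", ], s[s$group == "control", ],
                       covariates = c("age", "draw_time"))
    })
    names(out) <- c("set1", "set2")
    write.table(rbind(cbind(set = "set1", out$set1),
                      cbind(set = "set2", out$set2)),
                pathof("matched_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out
  })

  res$preprocess <- stage("preprocess", {
    out <- lapply(list(set1 = res$study$set1, set2 = res$study$set2),
                  function(tab) {
      kept <- qc_filter(tab, min_detect = cfg$preprocess$min_detect)
      identified <- subset_features(kept, which(kept$features$identified))
      list(filtered = kept, identified = identified,
           scaled = log_pareto(identified))
    })
    rsd <- rsd_report(res$study$set1$qc_replicates,
                      threshold = cfg$preprocess$rsd_threshold)
    write.table(rsd, pathof("rsd_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(out, list(rsd = rsd))
  })

  res$oplsda <- stage("oplsda", {
    out <- lapply(names(res$preprocess)[1:2], function(nm) {
      pp <- res$preprocess[[nm]]
      y <- pp$identified$samples$group
      sel <- select_n_orth(pp$scaled, y, max_orth = cfg$oplsda$max_orth,
                           folds = cfg$oplsda$folds)
      fit <- fit_oplsda(pp$scaled, y, n_orth = sel$n_orth)
      fit$q2 <- sel$q2
      perm <- permutation_test(pp$scaled, y, n_perm = cfg$oplsda$n_perm,
                               statistic = "Q2", folds = cfg$oplsda$folds,
                               n_orth = sel$n_orth,
                               seed = substream_seed(cfg$seed, 30L))
      vip <- setNames(fit$vip, colnames(pp$scaled))
      write.table(data.frame(feature_id = names(vip), vip = vip),
                  pathof(paste0("vip_", nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(set = nm, n_orth = sel$n_orth, r2x = fit$r2x, r2y = fit$r2y,
             q2 = fit$q2, permutation = list(
               statistic = "Q2", n_exceeding = perm$n_exceeding,
               n_permutations = perm$n_permutations,
               p_raw = perm$p_raw, p_value = perm$p_value),
             scores = as.vector(fit$scores)),
        pathof(paste0("oplsda_", nm, ".json")), auto_unbox = TRUE,
        digits = NA)
      list(fit = fit, selection = sel, permutation = perm, vip = vip)
    })
    names(out) <- c("set1", "set2")
    out
  })

  res$selection <- stage("select", {
    sel <- replicated_selection(res$oplsda$set1$vip, res$oplsda$set2$vip,
                                res$preprocess$set1$identified,
                                res$preprocess$set2$identified,
                                threshold = cfg$selection$vip_threshold)
    write.table(sel, pathof("selection.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ann <- res$preprocess$set1$identified$features
    enr <- superclass_enrichment(sel$feature_id[sel$selected], ann)
    write.table(enr, pathof("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(selection = sel, enrichment = enr)
  })

  res$network <- stage("network", {
    sel_ids <- res$selection$selection$feature_id[
      res$selection$selection$selected]
    if (length(sel_ids) < 3)
      stop("fewer than 3 replicated metabolites; no network to build")
    combined <- combine_sets(res$preprocess$set1$identified,
                             res$preprocess$set2$identified)
    sub <- subset_features(combined,
                           match(sel_ids, combined$features$feature_id))
    net <- build_network(sub, shrinkage = cfg$network$shrinkage,
                         edge_q = cfg$network$edge_q,
                         node_q = cfg$network$node_q,
                         display_cutoff = cfg$network$display_cutoff)
    write_network(net, pathof("network.graphml"),
                  pathof("network_edges.tsv"), pathof("network_nodes.tsv"))
    list(model = net, table = sub)
  })

  res$grs <- stage("grs", {
    study_cfg <- do.call(sim_config, cfg$sim)
    ref <- sim_reference_cohort(
      study_cfg, res$study$truth,
      n_cases = ceiling(cfg$grs$n_reference / 2),
      n_controls = floor(cfg$grs$n_reference / 2),
      seed = substream_seed(cfg$seed, 40L))
    ref_qc <- snp_qc(ref$panel)
    gwas <- gwas_logistic(ref_qc, ref$status[match(
      ref_qc$samples$sample_id, ref$panel$samples$sample_id)],
      age = ref$age[match(ref_qc$samples$sample_id,
                          ref$panel$samples$sample_id)])
    write.table(gwas, pathof("gwas.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    w <- grs_weights(gwas, p_threshold = cfg$grs$p_threshold)
    write.table(w, pathof("grs_weights.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    grs <- compute_grs(res$study$genotypes, w)
    write.table(data.frame(sample_id = names(grs), grs = grs),
                pathof("grs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cases <- res$study$genotypes$samples$group == "case"
    grp <- split_by_grs(grs[cases])
    list(reference = ref, gwas = gwas, weights = w, grs = grs,
         case_groups = grp,
         grs_means = tapply(grs[cases], grp, mean))
  })

  res$network_grs <- stage("network_grs", {
    tab <- res$network$table
    cases <- tab$samples$group == "case"
    sub <- feature_table(tab$abund[cases, , drop = FALSE],
                         tab$samples[cases, , drop = FALSE], tab$features)
    grp <- res$grs$case_groups[sub$samples$sample_id]
    net <- build_network(sub, groups = grp,
                         shrinkage = cfg$network$shrinkage,
                         edge_q = cfg$network$edge_q,
                         node_q = cfg$network$node_q,
                         display_cutoff = cfg$network$display_cutoff)
    write_network(net, nodes_path = pathof("network_grs_nodes.tsv"),
                  edges_path = pathof("network_grs_edges.tsv"))
    net
  })

  res$prediction <- stage("predict", {
    net <- res$network$model
    tab <- res$network$table
    mean_vip <- rowMeans(cbind(
      res$oplsda$set1$vip[tab$features$feature_id],
      res$oplsda$set2$vip[tab$features$feature_id]))
    sig_nodes <- net$nodes$node[!is.na(net$nodes$significant) &
                                  net$nodes$significant]
    pool <- if (length(sig_nodes) >= cfg$predict$n_markers) sig_nodes
            else tab$features$feature_id
    markers <- pool[order(-mean_vip[pool])][seq_len(
      min(cfg$predict$n_markers, length(pool)))]
    X <- log(impute_half_min(tab$abund[, markers, drop = FALSE]))
    y <- tab$samples$group
    grs <- res$grs$grs[tab$samples$sample_id]
    models <- list(
      markers = fit_predict_logistic(X, y),
      markers_reduced = fit_predict_logistic(X[, -1, drop = FALSE], y),
      markers_grs = fit_predict_logistic(cbind(X, grs = grs), y))
    for (nm in names(models))
      write.table(models[[nm]]$roc, pathof(paste0("roc_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(models, function(m) list(
        auc = m$auc, ci_low = m$auc_ci[1], ci_high = m$auc_ci[2],
        coefficients = as.list(m$coefficients))),
      pathof("predictions.json"), auto_unbox = TRUE, digits = NA)
    c(models, list(marker_ids = markers))
  })

  res$manifest <- stage("manifest", {
    files <- setdiff(list.files(out_dir), "manifest.json")
    man <- list(
      package_version = as.character(utils::packageVersion("metabrisk")),
      config = cfg,
      stage_seeds = list(simulate = cfg$sim$seed,
                         permutation = substream_seed(cfg$seed, 30L),
                         grs_reference = substream_seed(cfg$seed, 40L)),
      checksums = as.list(tools::md5sum(file.path(out_dir, files))))
    names(man$checksums) <- files
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })

  invisible(res)
}

#' Combine two study sets into one feature table
#'
#' Samples are stacked; the feature universes must match.
#'
#' @param t1,t2 [feature_table()]s with identical features.
#' @return a [feature_table()] over all samples.
#' @export
combine_sets <- function(t1, t2) {
  stopifnot(identical(t1$features$feature_id, t2$features$feature_id))
  feature_table(rbind(t1$abund, t2$abund), rbind(t1$samples, t2$samples),
                t1$features, qc_detection = t1$qc_detection)
}
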
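#' Replicated biomarker selection across two independent sets
#'
#' A feature is selected when its VIP exceeds the threshold in BOTH sets --
#' the replication filter that guards against set-specific artefacts. Fold
#' changes (case mean / control mean) are computed on the raw relative
#' abundance scale per set.
#'
#' @param vips1,vips2 named per-feature VIP vectors from the two sets; the
#'   feature universes must be identical.
#' @param table1,table2 optional [feature_table()]s (raw scale) used to add
#'   per-set fold changes.
#' @param threshold VIP threshold (default 1.0).
#' @return data.frame of class `selection_result`: `feature_id`, `vip_set1`,
#'   `vip_set2`, `fold_change_set1`, `fold_change_set2`, `selected`.
#' @export
replicated_selection <- function(vips1, vips2, table1 = NULL, table2 = NULL,
                                 threshold = 1.0) {
  if (is.null(names(vips1)) || is.null(names(vips2)))
    stop("VIP vectors must be named by feature")
  if (!identical(sort(names(vips1)), sort(names(vips2)))) {
    mism <- union(setdiff(names(vips1), names(vips2)),
                  setdiff(names(vips2), names(vips1)))
    stop("feature universes differ between sets: ",
         paste(head(mism, 10), collapse = ", "))
  }
  vips2 <- vips2[names(vips1)]
  out <- data.frame(feature_id = names(vips1),
                    vip_set1 = unname(vips1), vip_set2 = unname(vips2),
                    stringsAsFactors = FALSE)
  out$selected <- out$vip_set1 > threshold & out$vip_set2 > threshold
  if (!is.null(table1)) out$fold_change_set1 <-
      fold_change(table1)[out$feature_id]
  if (!is.null(table2)) out$fold_change_set2 <-
      fold_change(table2)[out$feature_id]
  class(out) <- c("selection_result", "data.frame")
  out
}

#' Case/control fold change of relative abundances
#'
#' Abundances are normalised to relative abundance per sample (each sample's
#' features divided by the sample total), then the ratio of case to control
#' feature means is returned.
#'
#' @param table a [feature_table()] with a `group` column of
#'   "case"/"control".
#' @return named vector of fold changes (case / control).
#' @export
fold_change <- function(table) {
  ab <- impute_half_min(table$abund)
  rel <- ab / rowSums(ab)
  grp <- table$samples$group
  setNames(colMeans(rel[grp == "case", , drop = FALSE]) /
             colMeans(rel[grp == "control", , drop = FALSE]),
           colnames(ab))
}

#' Chemical super-class over-representation of a selection
#'
#' One-sided hypergeometric test per super-class (is the class over-drawn in
#' the selection relative to the background universe?), with
#' Benjamini-Hochberg FDR across classes.
#'
#' @param selected character vector of selected feature ids.
#' @param annotation data.frame mapping `feature_id` to `super_class`.
#' @param background character vector of the feature universe (default: all
#'   annotated features). Every selected feature must be in the background.
#' @return data.frame: `super_class`, `hits`, `class_size`, `selection_size`,
#'   `background_size`, `p_value`, `fdr_q`, ordered by p.
#' @export
superclass_enrichment <- function(selected, annotation, background = NULL) {
  if (is.null(background)) background <- annotation$feature_id
  if (!all(selected %in% background))
    stop("selected features missing from background: ",
         paste(head(setdiff(selected, background), 5), collapse = ", "))
  if (length(selected) == 0)
    return(data.frame(super_class = character(), hits = integer(),
                      class_size = integer(), selection_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      fdr_q = numeric(), stringsAsFactors = FALSE))
  ann <- annotation[match(background, annotation$feature_id), ]
  if (any(is.na(ann$super_class) | is.na(ann$feature_id))) {
    warning("features without super-class annotation skipped")
    ann <- ann[!is.na(ann$super_class) & !is.na(ann$feature_id), ]
  }
  classes <- sort(unique(ann$super_class))
  n_bg <- nrow(ann)
  sel <- intersect(selected, ann$feature_id)
  n_sel <- length(sel)
  rows <- lapply(classes, function(cl) {
    in_class <- ann$feature_id[ann$super_class == cl]
    hits <- length(intersect(sel, in_class))
    m <- length(in_class)
    p <- stats::phyper(hits - 1, m, n_bg - m, n_sel, lower.tail = FALSE)
    data.frame(super_class = cl, hits = hits, class_size = m,
               selection_size = n_sel, background_size = n_bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}
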
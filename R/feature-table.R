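#' Construct a feature table
#'
#' The central container for a metabolomics study set: a samples x features
#' abundance matrix together with sample metadata, feature annotation and the
#' per-feature QC-injection detection fraction.
#'
#' @param abund numeric matrix, samples in rows, features in columns;
#'   nonnegative, `NA` allowed for missing abundances.
#' @param samples data.frame with one row per sample; must contain
#'   `sample_id`, `set`, `group` (factor or character, "case"/"control"),
#'   `age`, `draw_date`.
#' @param features data.frame with one row per feature; must contain
#'   `feature_id`; typically also `hmdb_like_id`, `mz`, `formula`,
#'   `super_class`, `identified`.
#' @param qc_detection numeric vector, per-feature fraction of QC injections
#'   in which the feature was detected (in `[0, 1]`), or `NULL`.
#' @param qc_replicates optional numeric matrix of repeated QC-sample
#'   injections (replicates x features) used for %RSD precision reporting.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abund, samples, features, qc_detection = NULL,
                          qc_replicates = NULL) {
  abund <- as.matrix(abund)
  stopifnot(nrow(abund) == nrow(samples), ncol(abund) == nrow(features))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("`samples` must contain at least sample_id and group")
  if (!"feature_id" %in% names(features))
    stop("`features` must contain feature_id")
  if (any(abund < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  if (!is.null(qc_detection)) {
    stopifnot(length(qc_detection) == ncol(abund),
              all(qc_detection >= 0 & qc_detection <= 1))
  }
  if (!is.null(qc_replicates)) {
    qc_replicates <- as.matrix(qc_replicates)
    stopifnot(ncol(qc_replicates) == ncol(abund))
  }
  rownames(abund) <- samples$sample_id
  colnames(abund) <- features$feature_id
  structure(list(abund = abund, samples = samples, features = features,
                 qc_detection = qc_detection, qc_replicates = qc_replicates),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  grp <- table(x$samples$group)
  cat("<feature_table> ", nrow(x$abund), " samples x ", ncol(x$abund),
      " features\n", sep = "")
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$qc_detection))
    cat("  QC detection fraction: median ",
        signif(median(x$qc_detection), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abund)

#' Subset a feature table by feature index, keeping metadata aligned
#'
#' @param table a [feature_table()]; @param idx feature indices to keep.
#' @return the reduced [feature_table()].
#' @export
subset_features <- function(table, idx) {
  feature_table(table$abund[, idx, drop = FALSE],
                table$samples,
                table$features[idx, , drop = FALSE],
                qc_detection = table$qc_detection[idx],
                qc_replicates =
                  if (!is.null(table$qc_replicates))
                    table$qc_replicates[, idx, drop = FALSE] else NULL)
}

#' Write / read a feature table as TSV
#'
#' The abundance file has one row per sample with leading columns
#' `sample_id`, `set`, `group`, `age`, `draw_date` followed by one column per
#' feature. The annotation file has one row per feature and carries the
#' QC detection fraction in a `qc_detection` column.
#'
#' @param table a [feature_table()].
#' @param abund_path,annot_path file paths for the two TSVs.
#' @return `write_feature_table` returns the paths invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(table, abund_path, annot_path) {
  meta_cols <- intersect(c("sample_id", "set", "group", "age", "draw_date"),
                         names(table$samples))
  out <- cbind(table$samples[meta_cols], as.data.frame(table$abund))
  write.table(out, abund_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- table$features
  if (!is.null(table$qc_detection)) ann$qc_detection <- table$qc_detection
  write.table(ann, annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(abund_path, annot_path))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(abund_path, annot_path) {
  raw <- read.delim(abund_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ann <- read.delim(annot_path, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("sample_id", "set", "group", "age", "draw_date"),
                         names(raw))
  abund <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  qc <- if ("qc_detection" %in% names(ann)) ann$qc_detection else NULL
  ann$qc_detection <- NULL
  feature_table(abund, raw[meta_cols], ann, qc_detection = qc)
}
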
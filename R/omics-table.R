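#' Construct an omics table
#'
#' Samples-by-features intensity or abundance matrix with a role per sample
#' (`subject`, `qc`, or `blank`), group labels on subjects only, and an
#' optional per-subject covariate table.
#'
#' @param values Numeric matrix or data frame, samples in rows, features in
#'   columns (feature names from column names).
#' @param sample_id Character vector of unique sample identifiers.
#' @param role Character vector: `"subject"`, `"qc"`, or `"blank"` per sample.
#'   Defaults to all subjects.
#' @param group Group label per sample; must be `NA` for non-subjects.
#' @param covariates Optional tibble of per-subject covariates (one row per
#'   subject sample, in sample order).
#' @return An object of class `omics_table`.
#' @export
omics_table <- function(values, sample_id, role = NULL, group = NULL,
                        covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) abort("`sample_id` must match rows of `values`.")
  if (anyDuplicated(sample_id)) abort("duplicated sample IDs.")
  role <- role %||% rep("subject", n)
  if (!all(role %in% c("subject", "qc", "blank"))) {
    abort("`role` entries must be subject, qc, or blank.")
  }
  group <- group %||% rep(NA_character_, n)
  if (any(!is.na(group[role != "subject"]))) {
    abort("group labels are only allowed on subject samples.")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("feature_%03d", seq_len(ncol(values)))
  }
  rownames(values) <- sample_id
  samples <- tibble(
    sample_id = sample_id, role = as.character(role),
    group = as.character(group)
  )
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (nrow(covariates) != sum(role == "subject")) {
      abort("`covariates` must have one row per subject sample.")
    }
  }
  structure(
    list(values = values, samples = samples, covariates = covariates),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(
    "<omics_table> ", nrow(x$values), " samples (",
    sum(x$samples$role == "subject"), " subjects, ",
    sum(x$samples$role == "qc"), " QC, ",
    sum(x$samples$role == "blank"), " blank) x ",
    ncol(x$values), " features\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.omics_table <- function(x, ...) {
  dplyr::bind_cols(x$samples, as_tibble(as.data.frame(x$values)))
}

#' @export
dim.omics_table <- function(x) dim(x$values)

# Subject-only submatrix and matching group labels.
subject_values <- function(ot) {
  keep <- ot$samples$role == "subject"
  list(
    values = ot$values[keep, , drop = FALSE],
    groups = ot$samples$group[keep],
    sample_id = ot$samples$sample_id[keep]
  )
}

# Feature subset, preserving metadata.
select_features <- function(ot, keep) {
  ot$values <- ot$values[, keep, drop = FALSE]
  ot
}

#' Aggregate ASV counts to genus-level relative abundances
#'
#' Sums denoised amplicon sequence variant (ASV) counts within each genus and
#' divides by the sample total, yielding the genus-level relative-abundance
#' table downstream statistics consume. ASVs without a genus assignment are
#' pooled into an `"unclassified"` bucket.
#'
#' @param asv_counts Numeric matrix or data frame of counts, samples x ASVs.
#' @param taxonomy Named character vector or two-column data frame mapping
#'   ASV names to genus labels (`NA` -> "unclassified").
#' @return A tibble with a `sample_id` column followed by one relative
#'   abundance column per genus; rows sum to one.
#' @export
#' @examples
#' counts <- matrix(c(10, 30, 60, 5, 15, 80), 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("asv1", "asv2", "asv3")))
#' aggregate_to_genus(counts, c(asv1 = "g1", asv2 = "g1", asv3 = "g2"))
aggregate_to_genus <- function(asv_counts, taxonomy) {
  counts <- as.matrix(asv_counts)
  if (is.data.frame(taxonomy)) {
    taxonomy <- setNames(as.character(taxonomy[[2]]), taxonomy[[1]])
  }
  asvs <- colnames(counts)
  if (is.null(asvs)) abort("`asv_counts` must have ASV column names.")
  genus <- unname(taxonomy[asvs])
  genus[is.na(genus) | genus == ""] <- "unclassified"
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    bad <- rownames(counts)[totals <= 0] %||% which(totals <= 0)
    abort(paste0("zero-total sample(s): ", paste(bad, collapse = ", ")))
  }
  agg <- t(rowsum(t(counts), group = genus))
  rel <- agg / totals
  dplyr::bind_cols(
    tibble(sample_id = rownames(counts) %||% paste0("S", seq_len(nrow(counts)))),
    as_tibble(as.data.frame(rel))
  )
}
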
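#' Metabolite quality-control, imputation, and normalization chain
#'
#' Applies the standard untargeted-metabolomics feature QC chain, in order:
#'
#' 1. **QC/blank ratio** — features whose mean pooled-QC intensity is less
#'    than `qc_blank_min` times their mean blank intensity are removed
#'    (chemical background).
#' 2. **QC RSD** — features whose relative standard deviation across QC
#'    replicates exceeds `rsd_max` percent are removed (irreproducible).
#' 3. **Prevalence** — features with a nonzero measurement in fewer than
#'    `prevalence_min` percent of subject samples are removed.
#' 4. **Imputation** — remaining zeros/missing values are replaced by 1/5 of
#'    the feature's minimum positive value.
#' 5. **QC normalization** — each feature is divided by the median of its QC
#'    intensities (a convention; no injection-order information is used).
#' 6. **Generalized log** — \eqn{g(x) = \log_2((x + \sqrt{x^2 + \lambda^2})/2)}
#'    with \eqn{\lambda} the feature's minimum positive value.
#' 7. **z-score** — each feature is standardized over subjects.
#'
#' Every removal is attributed to exactly one rule in the audit log. The
#' chain is idempotent: the output records the completed stages, and
#' re-running it on its own output returns it unchanged.
#'
#' @param ot An [omics_table()] with >= 2 QC samples and >= 1 blank.
#' @param qc_blank_min Minimum QC/blank mean-intensity ratio (default 3).
#' @param rsd_max Maximum QC relative standard deviation, percent (30).
#' @param prevalence_min Minimum percent of subjects with a nonzero value (80).
#' @param impute_factor Fraction of the minimum positive value used for
#'   imputation (1/5).
#' @return A list of class `metabolite_qc`: `table` (an [omics_table()] of
#'   subjects only, filtered and transformed), `audit` (tibble `feature`,
#'   `status`, `rule`, `value`), and `stages` (the completed stage names).
#' @export
metabolite_qc <- function(ot, qc_blank_min = 3, rsd_max = 30,
                          prevalence_min = 80, impute_factor = 1 / 5) {
  if (inherits(ot, "metabolite_qc")) {
    return(ot) # already processed: the chain is idempotent
  }
  if (!inherits(ot, "omics_table")) abort("`ot` must be an omics_table.")
  if (!is.null(attr(ot, "qc_stages"))) {
    return(structure(
      list(table = ot, audit = attr(ot, "qc_audit"), stages = attr(ot, "qc_stages")),
      class = "metabolite_qc"
    ))
  }
  roles <- ot$samples$role
  if (sum(roles == "qc") < 2 || sum(roles == "blank") < 1) {
    abort("need >= 2 QC samples and >= 1 blank.")
  }
  vals <- ot$values
  subj <- vals[roles == "subject", , drop = FALSE]
  qc <- vals[roles == "qc", , drop = FALSE]
  blank <- vals[roles == "blank", , drop = FALSE]
  feats <- colnames(vals)
  audit <- list()
  drop_rule <- rep(NA_character_, ncol(vals))
  drop_value <- rep(NA_real_, ncol(vals))
  alive <- rep(TRUE, ncol(vals))

  mark <- function(idx, rule, value) {
    newly <- idx & alive
    drop_rule[newly] <<- rule
    drop_value[newly] <<- value[newly]
    alive[newly] <<- FALSE
  }

  # 1. QC/blank mean ratio
  qc_mean <- colMeans(qc)
  blank_mean <- colMeans(blank)
  ratio <- ifelse(blank_mean > 0, qc_mean / blank_mean, Inf)
  mark(ratio < qc_blank_min, "qc_blank_ratio", ratio)

  # 2. QC RSD (%)
  rsd <- ifelse(qc_mean > 0, 100 * apply(qc, 2, sd) / qc_mean, Inf)
  mark(alive & rsd > rsd_max, "qc_rsd", rsd)

  # 3. subject prevalence (%)
  prevalence <- 100 * colMeans(subj > 0, na.rm = TRUE)
  mark(alive & prevalence < prevalence_min, "prevalence", prevalence)

  # features with no positive subject value cannot be imputed or scaled
  min_pos <- apply(subj, 2, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) == 0) NA_real_ else min(v)
  })
  mark(alive & !is.finite(min_pos), "no_positive_values", rep(NA_real_, ncol(vals)))

  sub2 <- subj[, alive, drop = FALSE]
  qc2 <- qc[, alive, drop = FALSE]
  mp <- min_pos[alive]

  # 4. impute zeros/missing with impute_factor * min positive
  for (j in seq_len(ncol(sub2))) {
    miss <- !is.finite(sub2[, j]) | sub2[, j] <= 0
    sub2[miss, j] <- impute_factor * mp[j]
  }

  # 5. per-feature division by the QC median
  qc_med <- apply(qc2, 2, median)
  bad_qc <- !is.finite(qc_med) | qc_med <= 0
  if (any(bad_qc)) {
    idx_full <- which(alive)[bad_qc]
    sel <- rep(FALSE, ncol(vals))
    sel[idx_full] <- TRUE
    mark(sel, "qc_median_nonpositive", rep(NA_real_, ncol(vals)))
    sub2 <- sub2[, !bad_qc, drop = FALSE]
    qc_med <- qc_med[!bad_qc]
  }
  sub2 <- sweep(sub2, 2, qc_med, `/`)

  # 6. glog with feature-wise lambda = minimum positive value
  lambda <- apply(sub2, 2, function(v) min(v[v > 0]))
  lam2 <- matrix(lambda^2, nrow(sub2), ncol(sub2), byrow = TRUE)
  sub2 <- log2((sub2 + sqrt(sub2^2 + lam2)) / 2)

  # 7. z-score over subjects (constant features are unscalable)
  sds <- apply(sub2, 2, sd)
  if (any(sds == 0)) {
    keep_names <- colnames(sub2)[sds == 0]
    sel <- rep(FALSE, ncol(vals))
    sel[match(keep_names, feats)] <- TRUE
    mark(sel, "zero_variance", rep(NA_real_, ncol(vals)))
    sub2 <- sub2[, sds > 0, drop = FALSE]
  }
  sub2 <- scale(sub2)

  audit <- tibble(
    feature = feats,
    status = ifelse(is.na(drop_rule), "kept", "removed"),
    rule = drop_rule,
    value = drop_value
  )
  keep_rows <- roles == "subject"
  out <- omics_table(
    sub2,
    sample_id = ot$samples$sample_id[keep_rows],
    role = rep("subject", sum(keep_rows)),
    group = ot$samples$group[keep_rows],
    covariates = ot$covariates
  )
  stages <- c(
    "qc_blank_ratio", "qc_rsd", "prevalence", "imputation",
    "qc_normalization", "glog", "zscore"
  )
  attr(out, "qc_stages") <- stages
  attr(out, "qc_audit") <- audit
  structure(
    list(table = out, audit = audit, stages = stages),
    class = "metabolite_qc"
  )
}

#' @export
print.metabolite_qc <- function(x, ...) {
  kept <- sum(x$audit$status == "kept")
  cat(sprintf(
    "<metabolite_qc> %d/%d features kept; removals: %s\n",
    kept, nrow(x$audit),
    paste(names(table(x$audit$rule)), table(x$audit$rule),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}
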
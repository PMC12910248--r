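#' Planted ground truth for a synthetic cohort
#'
#' Carries everything a synthetic multi-omics cohort is generated from:
#' group sizes, planted per-variable group effects, the serial-mediation path
#' coefficients, residual noise levels, and the seed. Generators return the
#' truth alongside the data so recovery tests can compare against it.
#'
#' @param group_sizes Named or unnamed integer vector, one entry per group,
#'   all >= 3. Unnamed vectors get groups `"G1"`, `"G2"`, ...
#' @param planted_effects Optional tibble with columns `assay` (`"taxa"` or
#'   `"metabolites"`), `variable` (1-based feature index), `group`, and
#'   `offset` (log-scale shift applied to that feature in that group).
#' @param mediation_paths Named numeric vector with elements `a1`, `a2`, `d`,
#'   `b1`, `b2`, `c_prime`: the unitless regression coefficients of the
#'   recursive system X -> M1 -> M2 -> Y.
#' @param noise_sds Named numeric vector `m1`, `m2`, `y` of residual standard
#'   deviations (>= 0) for the three structural equations.
#' @param seed Integer seed; a fixed seed regenerates the cohort bit for bit.
#' @return An object of class `cohort_truth`.
#' @export
#' @examples
#' cohort_truth(c(HC = 56, `WMH-NC` = 40, `WMH-CI` = 49))
cohort_truth <- function(group_sizes,
                         planted_effects = NULL,
                         mediation_paths = c(
                           a1 = 0.5, a2 = 0.3, d = 0.4,
                           b1 = 0.3, b2 = 0.4, c_prime = 0.2
                         ),
                         noise_sds = c(m1 = 1, m2 = 1, y = 1),
                         seed = 1L) {
  group_sizes <- round(group_sizes)
  if (length(group_sizes) < 1 || any(group_sizes < 3)) {
    abort("all `group_sizes` must be >= 3.")
  }
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  needed <- c("a1", "a2", "d", "b1", "b2", "c_prime")
  if (!all(needed %in% names(mediation_paths))) {
    abort(paste0(
      "`mediation_paths` must name ",
      paste(needed, collapse = ", ")
    ))
  }
  if (!all(c("m1", "m2", "y") %in% names(noise_sds))) {
    abort("`noise_sds` must name m1, m2, y.")
  }
  noise_sds <- noise_sds[c("m1", "m2", "y")]
  if (any(!is.finite(noise_sds)) || any(noise_sds < 0)) {
    abort("`noise_sds` must be finite and >= 0.")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as_tibble(planted_effects)
    req <- c("assay", "variable", "group", "offset")
    if (!all(req %in% names(planted_effects))) {
      abort("`planted_effects` needs columns assay, variable, group, offset.")
    }
    bad <- setdiff(planted_effects$group, names(group_sizes))
    if (length(bad) > 0) {
      abort(paste0(
        "planted effect group(s) not in `group_sizes`: ",
        paste(unique(bad), collapse = ", ")
      ))
    }
  }
  structure(
    list(
      group_sizes = group_sizes,
      planted_effects = planted_effects,
      mediation_paths = mediation_paths[needed],
      noise_sds = noise_sds,
      seed = as.integer(seed)
    ),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(
    "<cohort_truth> groups:",
    paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = " "),
    "\n paths:",
    paste(sprintf("%s=%.3g", names(x$mediation_paths), x$mediation_paths),
      collapse = " "
    ),
    "\n noise SDs:",
    paste(sprintf("%s=%.3g", names(x$noise_sds), x$noise_sds), collapse = " "),
    " seed:", x$seed, "\n"
  )
  invisible(x)
}

#' Generate a subject table with a planted serial mediation structure
#'
#' Draws `n` subjects from the linear recursive system
#' \deqn{M_1 = a_1 X + \gamma_1^T C + \epsilon_1}
#' \deqn{M_2 = a_2 X + d M_1 + \gamma_2^T C + \epsilon_2}
#' \deqn{Y = c' X + b_1 M_1 + b_2 M_2 + \gamma_3^T C + \epsilon_3}
#' with standard-normal X, Gaussian residuals at the truth's `noise_sds`, and
#' `n_covariates` confounders C (the first binary 0/1, the rest continuous)
#' whose coefficients are drawn once from the seeded stream.
#'
#' @param truth A [cohort_truth()].
#' @param n Number of subjects (>= 10).
#' @param n_covariates Number of covariate columns (0 for none).
#' @return A tibble with columns `x`, `m1`, `m2`, `y`, and `c1..ck`, carrying
#'   the generating `cohort_truth` in attribute `"truth"`.
#' @export
#' @examples
#' cohort <- gen_mediation_cohort(cohort_truth(c(20, 20, 20)), n = 60)
#' head(cohort)
gen_mediation_cohort <- function(truth, n, n_covariates = 4) {
  if (!inherits(truth, "cohort_truth")) abort("`truth` must be a cohort_truth.")
  if (n < 10) abort("`n` must be >= 10.")
  p <- truth$mediation_paths
  s <- truth$noise_sds
  with_local_seed(truth$seed, {
    x <- rnorm(n)
    if (n_covariates > 0) {
      C <- cbind(
        rbinom(n, 1, 0.5),
        if (n_covariates > 1) {
          matrix(rnorm(n * (n_covariates - 1)), n)
        }
      )
      colnames(C) <- paste0("c", seq_len(n_covariates))
      gamma <- matrix(rnorm(3 * n_covariates, sd = 0.3), nrow = n_covariates)
    } else {
      C <- NULL
      gamma <- matrix(0, 0, 3)
    }
    cov_term <- function(j) if (is.null(C)) 0 else drop(C %*% gamma[, j])
    m1 <- p["a1"] * x + cov_term(1) + rnorm(n, sd = s["m1"])
    m2 <- p["a2"] * x + p["d"] * m1 + cov_term(2) + rnorm(n, sd = s["m2"])
    y <- p["c_prime"] * x + p["b1"] * m1 + p["b2"] * m2 + cov_term(3) +
      rnorm(n, sd = s["y"])
    out <- tibble(x = x, m1 = m1, m2 = m2, y = y)
    if (!is.null(C)) out <- dplyr::bind_cols(out, as_tibble(as.data.frame(C)))
    attr(out, "truth") <- truth
    out
  })
}

#' Generate paired taxa and metabolite tables with planted group effects
#'
#' Taxa: per-sample log-normal abundances closed to sum one (planted group
#' offsets are exact shifts on the log scale before closure). Metabolites:
#' log-normal intensities with pooled-QC replicates at a controllable
#' relative standard deviation, instrument blanks at a controllable
#' background ratio, and controllable per-feature missingness, so every
#' downstream quality-control rule has both passing and failing features.
#'
#' @param truth A [cohort_truth()]; `truth$planted_effects` rows with
#'   `assay == "taxa"` / `"metabolites"` shift feature `variable` in `group`
#'   by `offset` on the natural-log scale.
#' @param n_taxa Number of genera (>= 5).
#' @param n_metabolites Number of metabolite features (>= 10).
#' @param n_qc,n_blank Number of pooled-QC and blank injections.
#' @param qc_rsd Scalar or per-feature QC relative standard deviation
#'   (fraction, e.g. 0.1 = 10%).
#' @param blank_ratio Scalar or per-feature blank/QC mean intensity ratio.
#' @param missing_rate Scalar or per-feature probability that a subject
#'   measurement is missing (recorded as 0).
#' @param taxa_log_sd Between-sample log-scale SD of taxa abundances.
#' @return A list with elements `taxa` and `metabolites` (both
#'   [omics_table()]s) and `truth`.
#' @export
gen_group_omics <- function(truth, n_taxa = 50, n_metabolites = 100,
                            n_qc = 6, n_blank = 3,
                            qc_rsd = 0.1, blank_ratio = 0.05,
                            missing_rate = 0.02, taxa_log_sd = 0.5) {
  if (!inherits(truth, "cohort_truth")) abort("`truth` must be a cohort_truth.")
  if (n_taxa < 5) abort("`n_taxa` must be >= 5.")
  if (n_metabolites < 10) abort("`n_metabolites` must be >= 10.")
  if (n_qc < 2 || n_blank < 1) abort("need >= 2 QC and >= 1 blank sample.")
  sizes <- truth$group_sizes
  n_sub <- sum(sizes)
  groups <- rep(names(sizes), sizes)
  qc_rsd <- rep_len(qc_rsd, n_metabolites)
  blank_ratio <- rep_len(blank_ratio, n_metabolites)
  missing_rate <- rep_len(missing_rate, n_metabolites)

  offsets <- function(assay, n_feat) {
    # subjects x features matrix of planted log-scale shifts
    out <- matrix(0, n_sub, n_feat)
    pe <- truth$planted_effects
    if (!is.null(pe)) {
      pe <- pe[pe$assay == assay, , drop = FALSE]
      for (i in seq_len(nrow(pe))) {
        out[groups == pe$group[i], pe$variable[i]] <-
          out[groups == pe$group[i], pe$variable[i]] + pe$offset[i]
      }
    }
    out
  }

  with_local_seed(derive_seed(truth$seed, "omics"), {
    ## taxa: log-normal then closure
    base_taxa <- rnorm(n_taxa, mean = 0, sd = 1.5)
    log_ab <- matrix(rnorm(n_sub * n_taxa, sd = taxa_log_sd),
      n_sub,
      byrow = FALSE
    ) + matrix(base_taxa, n_sub, n_taxa, byrow = TRUE) + offsets("taxa", n_taxa)
    ab <- exp(log_ab)
    ab <- ab / rowSums(ab)
    colnames(ab) <- sprintf("genus_%02d", seq_len(n_taxa))
    sub_ids <- sprintf("S%03d", seq_len(n_sub))
    rownames(ab) <- sub_ids
    taxa <- omics_table(ab,
      sample_id = sub_ids, role = rep("subject", n_sub),
      group = groups
    )

    ## metabolites: log-normal intensities, QC replicates, blanks, missingness
    feat_mean <- runif(n_metabolites, 11, 15) # log peak areas ~ 6e4..3e6
    subj <- exp(
      matrix(feat_mean, n_sub, n_metabolites, byrow = TRUE) +
        matrix(rnorm(n_sub * n_metabolites, sd = 0.4), n_sub) +
        offsets("metabolites", n_metabolites)
    )
    miss <- matrix(
      rbinom(n_sub * n_metabolites, 1,
        prob = rep(missing_rate, each = n_sub)
      ) == 1, n_sub
    )
    subj[miss] <- 0
    qc <- exp(matrix(feat_mean, n_qc, n_metabolites, byrow = TRUE)) *
      matrix(
        pmax(0, 1 + rnorm(n_qc * n_metabolites,
          sd = rep(qc_rsd, each = n_qc)
        )),
        n_qc
      )
    blank <- exp(matrix(feat_mean, n_blank, n_metabolites, byrow = TRUE)) *
      matrix(rep(blank_ratio, each = n_blank), n_blank) *
      matrix(pmax(0, 1 + rnorm(n_blank * n_metabolites, sd = 0.1)), n_blank)
    values <- rbind(subj, qc, blank)
    colnames(values) <- sprintf("met_%03d", seq_len(n_metabolites))
    ids <- c(sub_ids, sprintf("QC%02d", seq_len(n_qc)), sprintf("BL%02d", seq_len(n_blank)))
    rownames(values) <- ids
    mets <- omics_table(values,
      sample_id = ids,
      role = c(rep("subject", n_sub), rep("qc", n_qc), rep("blank", n_blank)),
      group = c(groups, rep(NA_character_, n_qc + n_blank))
    )
    list(taxa = taxa, metabolites = mets, truth = truth)
  })
}
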
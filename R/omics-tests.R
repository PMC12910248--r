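#' Covariate-adjusted Kruskal-Wallis test
#'
#' Rank test for a group difference after removing covariate effects: the
#' response is residualized on the covariates by ordinary least squares
#' (binary covariates coded 0/1), the residuals are mid-ranked, and the
#' Kruskal-Wallis H statistic with tie correction is computed on the
#' residual ranks (chi-squared p-value with k - 1 df). With no covariates
#' this is the classical Kruskal-Wallis test.
#'
#' @param data Data frame with one row per subject.
#' @param y Response column name.
#' @param group Group column name (>= 3 subjects per group).
#' @param covariates Character vector of covariate column names, or `NULL`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`, and the
#'   `adjustment` convention applied.
#' @export
#' @examples
#' df <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), 10), age = rnorm(30))
#' adjusted_kruskal_wallis(df, "y", "g", "age")
adjusted_kruskal_wallis <- function(data, y, group, covariates = NULL) {
  yv <- as.numeric(pull_col(data, y))
  gv <- as.factor(pull_col(data, group))
  keep <- is.finite(yv) & !is.na(gv)
  C <- covariate_matrix(data, covariates)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  yv <- yv[keep]
  gv <- droplevels(gv[keep])
  C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  if (any(table(gv) < 3)) abort("need >= 3 subjects per group.")
  check_full_rank(C)
  resid <- ols_residuals(yv, C)
  kt <- kruskal.test(resid, gv)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n = length(yv),
    adjustment = if (is.null(C)) {
      "none"
    } else {
      paste0("OLS residualization on ", paste(covariates, collapse = ", "))
    }
  )
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z-tests on pooled mid-ranks following a Kruskal-Wallis test,
#' with the tie correction
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' where \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over tie groups. Adjusted
#' p-values are Bonferroni: `min(1, m p)` with `m` the number of pairwise
#' comparisons (3 for three groups).
#'
#' @inheritParams adjusted_kruskal_wallis
#' @param adjust_factor Bonferroni multiplier; defaults to the number of
#'   pairs and is recomputed (with a message) if it understates them.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(data, y, group, adjust_factor = NULL) {
  yv <- as.numeric(pull_col(data, y))
  gv <- as.factor(pull_col(data, group))
  keep <- is.finite(yv) & !is.na(gv)
  yv <- yv[keep]
  gv <- droplevels(gv[keep])
  k <- nlevels(gv)
  if (k < 2) abort("need >= 2 groups.")
  n_pairs <- k * (k - 1) / 2
  if (is.null(adjust_factor)) {
    adjust_factor <- n_pairs
  } else if (adjust_factor < n_pairs) {
    inform(sprintf(
      "declared Bonferroni factor %d < %d pairwise comparisons; using %d.",
      adjust_factor, n_pairs, n_pairs
    ))
    adjust_factor <- n_pairs
  }
  N <- length(yv)
  rk <- rank(yv) # mid-ranks
  ties <- table(yv)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, gv, mean)
  ns <- table(gv)
  pairs <- utils::combn(levels(gv), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]
    j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    tibble(
      group1 = i, group2 = j, z = z, p_value = p,
      p_adjusted = pmin(1, adjust_factor * p)
    )
  })
  dplyr::bind_rows(rows)
}

#' One-way ANOVA from group summary statistics
#'
#' Exact algebraic reconstruction of the one-way F statistic from per-group
#' means, standard deviations, and sizes:
#' \eqn{SSB = \sum n_i (\bar x_i - \bar x)^2},
#' \eqn{SSW = \sum (n_i - 1) s_i^2}, \eqn{F = MSB / MSW}. Useful for
#' recomputing the statistics of a published demographics table from its
#' printed summaries.
#'
#' @param means,sds,ns Numeric vectors of per-group means, SDs (>= 0), and
#'   sizes (>= 2), one entry per group (>= 2 groups).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' oneway_anova_summary(c(61.50, 63.75, 64.94), c(7.52, 6.84, 7.88), c(56, 40, 49))
oneway_anova_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    abort("`means`, `sds`, `ns` must have one entry per group (>= 2 groups).")
  }
  if (any(sds < 0)) abort("standard deviations must be >= 0.")
  if (any(ns < 2)) abort("each group needs n >= 2.")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  tibble(statistic = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' One-way ANOVA from raw data
#'
#' Raw-data overload of [oneway_anova_summary()]: computes the per-group
#' summaries and feeds them through the same algebra, so the two paths agree
#' to machine precision.
#'
#' @inheritParams adjusted_kruskal_wallis
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`, `n`.
#' @export
oneway_anova <- function(data, y, group) {
  yv <- as.numeric(pull_col(data, y))
  gv <- as.factor(pull_col(data, group))
  keep <- is.finite(yv) & !is.na(gv)
  yv <- yv[keep]
  gv <- droplevels(gv[keep])
  means <- tapply(yv, gv, mean)
  sds <- tapply(yv, gv, sd)
  ns <- tapply(yv, gv, length)
  out <- oneway_anova_summary(as.numeric(means), as.numeric(sds), as.numeric(ns))
  out$n <- length(yv)
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction (the convention that
#' reproduces printed cohort-table statistics), df = (r - 1)(c - 1).
#'
#' @param counts Contingency table (matrix), 2 x k or larger; no zero
#'   marginals.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' group_chisq(rbind(yes = c(12, 26, 26), no = c(44, 14, 23)))
group_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) < 2)) abort("`counts` must be at least 2 x 2.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero marginal in the contingency table.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}
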
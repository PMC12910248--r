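#' Published summary statistics of a three-group WMH cohort
#'
#' Per-group summary statistics (counts for categorical variables; mean,
#' SD, n for continuous ones) of a published cohort of healthy controls
#' (HC), white-matter-hyperintensity participants with normal cognition
#' (WMH-NC), and with cognitive impairment (WMH-CI). Because the one-way
#' ANOVA F and Pearson chi-square statistics are exact functions of these
#' summaries, the cohort's demographics-table statistics can be recomputed
#' from them with [oneway_anova_summary()] and [group_chisq()] without any
#' subject-level data.
#'
#' @param type `"categorical"` (variable, group, n_yes, n_total) or
#'   `"continuous"` (variable, group, mean, sd, n).
#' @return A tibble.
#' @export
#' @examples
#' cc <- cohort_summaries("continuous")
#' age <- cc[cc$variable == "age", ]
#' oneway_anova_summary(age$mean, age$sd, age$n)
cohort_summaries <- function(type = c("categorical", "continuous")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0("cohort_", type, ".tsv"),
    package = "glymphomics", mustWork = TRUE
  )
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Recompute a cohort demographics table from its summaries
#'
#' Runs [group_chisq()] on every categorical variable (yes/no by group) and
#' [oneway_anova_summary()] on every continuous variable of a summary pair
#' as returned by [cohort_summaries()].
#'
#' @param categorical Tibble with columns variable, group, n_yes, n_total.
#' @param continuous Tibble with columns variable, group, mean, sd, n.
#' @return A tibble: `variable`, `test` ("chi-square" or "anova"),
#'   `statistic`, `p_value`.
#' @export
demographics_table_stats <- function(categorical = cohort_summaries("categorical"),
                                     continuous = cohort_summaries("continuous")) {
  cat_rows <- purrr::map_dfr(unique(categorical$variable), function(v) {
    sub <- categorical[categorical$variable == v, ]
    tab <- rbind(yes = sub$n_yes, no = sub$n_total - sub$n_yes)
    res <- group_chisq(tab)
    tibble(
      variable = v, test = "chi-square",
      statistic = res$statistic, p_value = res$p_value
    )
  })
  cont_rows <- purrr::map_dfr(unique(continuous$variable), function(v) {
    sub <- continuous[continuous$variable == v, ]
    res <- oneway_anova_summary(sub$mean, sub$sd, sub$n)
    tibble(
      variable = v, test = "anova",
      statistic = res$statistic, p_value = res$p_value
    )
  })
  dplyr::bind_rows(cat_rows, cont_rows)
}
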
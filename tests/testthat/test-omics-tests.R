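test_that("adjusted Kruskal-Wallis without covariates is the classical test", {
  # no-tie worked instance: groups {1,2,3}, {4,5,6}, {7,8,9}; H by the
  # direct rank formula is 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1) = 7.2
  df <- data.frame(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
  res <- adjusted_kruskal_wallis(df, "y", "g")
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$adjustment, "none")
  # and equals stats::kruskal.test on random data with ties
  df2 <- withr::with_seed(3, data.frame(
    y = round(rnorm(45), 1), g = rep(c("a", "b", "c"), each = 15)
  ))
  res2 <- adjusted_kruskal_wallis(df2, "y", "g")
  ref <- kruskal.test(df2$y, factor(df2$g))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_value, ref$p.value)
})

test_that("covariate-driven responses keep the nominal type-I error", {
  n_rep <- 500
  rej <- 0
  for (s in seq_len(n_rep)) {
    df <- withr::with_seed(1000 + s, {
      d <- data.frame(
        g = rep(c("a", "b", "c"), each = 20),
        c1 = rnorm(60), c2 = rbinom(60, 1, 0.5)
      )
      d$y <- 2 * d$c1 + 0.5 * d$c2 + rnorm(60)
      d
    })
    p <- adjusted_kruskal_wallis(df, "y", "g", c("c1", "c2"))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("the adjusted H statistic has the chi-squared mean under the null", {
  hs <- vapply(1:300, function(s) {
    df <- withr::with_seed(s, data.frame(
      y = rnorm(60), g = sample(rep(c("a", "b", "c"), each = 20)), c1 = rnorm(60)
    ))
    adjusted_kruskal_wallis(df, "y", "g", "c1")$statistic
  }, 0)
  expect_equal(mean(hs), 2, tolerance = 0.25) # k - 1 = 2
})

test_that("collinear covariates are rejected by name", {
  df <- data.frame(
    y = rnorm(30), g = rep(c("a", "b", "c"), 10),
    c1 = rnorm(30)
  )
  df$c2 <- 2 * df$c1
  expect_error(adjusted_kruskal_wallis(df, "y", "g", c("c1", "c2")), "c2")
})

test_that("Dunn post hoc behaves on identical and shifted groups", {
  df_same <- data.frame(y = rep(1:10, 2), g = rep(c("a", "b"), each = 10))
  res <- dunn_posthoc(df_same, "y", "g")
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  # adjusted p never below raw p
  df3 <- withr::with_seed(8, data.frame(
    y = c(rnorm(40), rnorm(40), rnorm(40) + 2),
    g = rep(c("a", "b", "c"), each = 40)
  ))
  res3 <- dunn_posthoc(df3, "y", "g")
  expect_true(all(res3$p_adjusted >= res3$p_value))
  expect_equal(nrow(res3), 3)
  # only the two pairs involving the shifted group are significant
  sig <- res3$p_adjusted < 0.05
  involved <- res3$group1 == "c" | res3$group2 == "c"
  expect_identical(sig, involved)
  # an understated adjustment factor is recomputed with a message
  expect_message(dunn_posthoc(df3, "y", "g", adjust_factor = 1), "using 3")
})

test_that("summary-statistic ANOVA agrees with the raw-data path and lm", {
  df <- withr::with_seed(21, data.frame(
    y = rnorm(90, mean = rep(c(0, 0.5, 1), each = 30)),
    g = rep(c("a", "b", "c"), each = 30)
  ))
  raw <- oneway_anova(df, "y", "g")
  means <- tapply(df$y, df$g, mean)
  sds <- tapply(df$y, df$g, sd)
  ns <- tapply(df$y, df$g, length)
  summ <- oneway_anova_summary(as.numeric(means), as.numeric(sds), as.numeric(ns))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  ref <- anova(lm(y ~ g, data = df))
  expect_equal(summ$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(summ$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # equal means give F = 0
  expect_equal(oneway_anova_summary(c(1, 1, 1), c(1, 2, 3), c(5, 5, 5))$statistic, 0)
  expect_error(oneway_anova_summary(c(1, 2), c(-1, 1), c(5, 5)), ">= 0")
})

test_that("chi-square uses no continuity correction and respects symmetry", {
  tab <- rbind(yes = c(12, 26, 26), no = c(44, 14, 23))
  res <- group_chisq(tab)
  expect_equal(res$df, 2)
  # independent table built from margins gives exactly zero
  marg_r <- c(30, 70)
  marg_c <- c(40, 60)
  indep <- outer(marg_r, marg_c) / 100
  expect_equal(group_chisq(indep)$statistic, 0, tolerance = 1e-12)
  # swapping rows of a 2x2 leaves the statistic unchanged
  t22 <- rbind(c(10, 20), c(30, 15))
  expect_equal(group_chisq(t22)$statistic, group_chisq(t22[2:1, ])$statistic)
  expect_error(group_chisq(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("genus aggregation closes counts to relative abundances", {
  counts <- matrix(c(10, 30, 60, 5, 15, 80), 2,
    byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("asv1", "asv2", "asv3"))
  )
  tax <- c(asv1 = "g1", asv2 = "g1", asv3 = "g2")
  rel <- aggregate_to_genus(counts, tax)
  expect_equal(rel$g1[rel$sample_id == "s1"], 0.4)
  expect_equal(rowSums(rel[, -1]), c(1, 1), ignore_attr = TRUE)
  # single genus: abundance 1 everywhere
  rel1 <- aggregate_to_genus(counts, c(asv1 = "g", asv2 = "g", asv3 = "g"))
  expect_true(all(rel1$g == 1))
  # unassigned ASVs pool into "unclassified"
  rel2 <- aggregate_to_genus(counts, c(asv1 = "g1", asv2 = NA, asv3 = "g2"))
  expect_true("unclassified" %in% names(rel2))
  expect_error(aggregate_to_genus(rbind(counts, s3 = c(0, 0, 0)), tax), "s3")
})

test_that("published cohort summaries reproduce the printed table statistics", {
  stats <- demographics_table_stats()
  get <- function(v) stats$statistic[stats$variable == v]
  expect_equal(get("hypertension"), 20.356, tolerance = 0.001)
  expect_equal(get("age"), 2.879, tolerance = 0.01)
  expect_equal(get("moca"), 76.705, tolerance = 0.01)
})
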
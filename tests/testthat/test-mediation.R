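test_that("partial Spearman equals the classical rank formula without covariates", {
  xy <- withr::with_seed(12, data.frame(a = rnorm(50)))
  xy$b <- xy$a + rnorm(50)
  res <- partial_spearman(xy, "a", "b")
  expect_equal(res$rho, cor(xy$a, xy$b, method = "spearman"), tolerance = 1e-12)
  # monotone transform: rho = 1
  xy$c <- exp(xy$a)
  expect_equal(partial_spearman(xy, "a", "c")$rho, 1)
  # constant input: missing result
  xy$k <- 1
  expect_true(is.na(partial_spearman(xy, "a", "k")$rho))
})

test_that("partial Spearman holds its nominal size under a covariate-driven null", {
  n_rep <- 500
  rej <- 0
  for (s in seq_len(n_rep)) {
    df <- withr::with_seed(7000 + s, {
      d <- data.frame(x = rnorm(40), z = rnorm(40))
      d$y <- d$z # y is the covariate exactly; x independent
      d
    })
    p <- partial_spearman(df, "x", "y", "z")$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("the exact-Y chain recovers b-paths exactly and errors when degenerate", {
  # noise on the mediator equations, none on Y: b1, b2, c' are exact
  tr <- cohort_truth(c(10, 10),
    mediation_paths = c(a1 = 0.5, a2 = 0, d = 0.8, b1 = 0, b2 = 0.4, c_prime = 0),
    noise_sds = c(m1 = 1, m2 = 1, y = 0), seed = 17
  )
  coh <- gen_mediation_cohort(tr, n = 80, n_covariates = 0)
  fit <- serial_mediation(coh, "x", "m1", "m2", "y", n_boot = 0)
  paths <- setNames(fit$paths$estimate, fit$paths$term)
  expect_equal(unname(paths["b1"]), 0, tolerance = 1e-10)
  expect_equal(unname(paths["b2"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(paths["c_prime"]), 0, tolerance = 1e-10)
  # ie3 = a1_hat * d_hat * b2 equals the total effect (all other paths zero)
  est <- setNames(fit$effects$estimate, fit$effects$effect)
  expect_equal(unname(est["ie3"] + est["ie2"]), unname(est["c"]), tolerance = 1e-10)

  # a fully noise-free system is exactly collinear and must refuse to fit
  tr0 <- cohort_truth(c(10, 10),
    mediation_paths = c(a1 = 0.5, a2 = 0, d = 0.8, b1 = 0, b2 = 0.4, c_prime = 0),
    noise_sds = c(m1 = 0, m2 = 0, y = 0), seed = 17
  )
  coh0 <- gen_mediation_cohort(tr0, n = 50, n_covariates = 0)
  expect_error(serial_mediation(coh0, "x", "m1", "m2", "y", n_boot = 0), "singular")
})

test_that("the decomposition identity holds on arbitrary data with covariates", {
  for (s in 1:25) {
    df <- withr::with_seed(300 + s, data.frame(
      x = rnorm(60), m1 = rnorm(60), m2 = rnorm(60), y = rnorm(60),
      c1 = rbinom(60, 1, 0.5), c2 = rnorm(60)
    ))
    fit <- serial_mediation(df, "x", "m1", "m2", "y",
      covariates = c("c1", "c2"), n_boot = 0
    )
    expect_lt(fit$identity_gap, 1e-10)
  }
})

test_that("bootstrap intervals are deterministic given the seed", {
  coh <- gen_mediation_cohort(cohort_truth(c(20, 20), seed = 4), n = 100)
  f1 <- serial_mediation(coh, "x", "m1", "m2", "y",
    covariates = c("c1", "c2"), n_boot = 500, seed = 77
  )
  f2 <- serial_mediation(coh, "x", "m1", "m2", "y",
    covariates = c("c1", "c2"), n_boot = 500, seed = 77
  )
  expect_identical(f1$effects, f2$effects)
  # point estimate inside its percentile interval on a healthy fit
  expect_true(all(
    f1$effects$conf_low <= f1$effects$estimate + 1e-12 &
      f1$effects$estimate <= f1$effects$conf_high + 1e-12
  ))
})

test_that("an in-sample-orthogonal covariate leaves coefficients unchanged", {
  df <- withr::with_seed(5, data.frame(
    x = rnorm(50), m1 = rnorm(50), m2 = rnorm(50), y = rnorm(50)
  ))
  base <- serial_mediation(df, "x", "m1", "m2", "y", n_boot = 0)
  # build a covariate exactly orthogonal (in sample) to every variable
  Q <- qr.Q(qr(cbind(1, df$x, df$m1, df$m2, df$y, rnorm(50))))
  df$c_orth <- Q[, 6]
  with_cov <- serial_mediation(df, "x", "m1", "m2", "y",
    covariates = "c_orth", n_boot = 0
  )
  expect_equal(base$paths$estimate, with_cov$paths$estimate, tolerance = 1e-10)
})

test_that("the mediation grid is keyed, reproducible, and order-sensitive", {
  tr <- cohort_truth(c(30, 30),
    mediation_paths = c(a1 = 0.6, a2 = 0.1, d = 0.7, b1 = 0.2, b2 = 0.5, c_prime = 0.1),
    seed = 21
  )
  coh <- gen_mediation_cohort(tr, n = 300, n_covariates = 2)
  grid_fwd <- mediation_grid(coh,
    x_set = "x", m1_set = "m1", m2_set = "m2", y_set = "y",
    covariates = c("c1", "c2"), n_boot = 50, seed = 9
  )
  grid_rev <- mediation_grid(coh,
    x_set = "x", m1_set = "m2", m2_set = "m1", y_set = "y",
    covariates = c("c1", "c2"), n_boot = 50, seed = 9
  )
  fwd <- grid_fwd[grid_fwd$effect == "ie3", ]
  rev <- grid_rev[grid_rev$effect == "ie3", ]
  # serial order matters when d != 0: the two orderings give different ie3
  expect_gt(abs(fwd$estimate - rev$estimate), 1e-6)

  # single combination reproduces serial_mediation with the derived child seed
  single <- mediation_grid(coh,
    x_set = "x", m1_set = "m1", m2_set = "m2", y_set = "y",
    covariates = c("c1", "c2"), n_boot = 50, seed = 9
  )
  direct <- serial_mediation(coh, "x", "m1", "m2", "y",
    covariates = c("c1", "c2"),
    n_boot = 50, seed = derive_seed(9, "x", "m1", "m2", "y")
  )
  expect_equal(single$estimate, direct$effects$estimate)
  expect_equal(single$conf_low, direct$effects$conf_low)

  expect_error(
    mediation_grid(coh, "nope", "m1", "m2", "y"),
    "nope"
  )
})
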
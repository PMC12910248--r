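test_that("perfect anticorrelation at zero lag is identified", {
  x <- withr::with_seed(1, as.numeric(scale(rnorm(100))))
  cc <- bold_csf_ccf(x, -x, tr = 2)
  expect_equal(cc$r[cc$lag == 0], -1, tolerance = 1e-12)
  expect_equal(attr(cc, "chosen_lag"), 0)
  expect_true(all(cc$r >= -1 & cc$r <= 1, na.rm = TRUE))
})

test_that("swapping the series negates the lag axis", {
  tr <- coupling_phantom_truth(lag_true = 4, amplitude = 0.8, tr = 2)
  ser <- gen_coupling_series(tr, seed = 9)
  ab <- bold_csf_ccf(ser$gbold, ser$csf, tr = 2)
  ba <- bold_csf_ccf(ser$csf, ser$gbold, tr = 2)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("coupling strength is invariant under affine rescaling of either series", {
  tr <- coupling_phantom_truth(lag_true = 4, amplitude = 0.8, tr = 2)
  ser <- gen_coupling_series(tr, seed = 3)
  cc <- bold_csf_ccf(ser$gbold, ser$csf, tr = 2)
  cc2 <- bold_csf_ccf(5 * ser$gbold - 2, 0.1 * ser$csf + 7, tr = 2)
  expect_equal(cc$r, cc2$r, tolerance = 1e-12)
})

test_that("group-level lag selection recovers the planted +4 s lag", {
  tr <- coupling_phantom_truth(lag_true = 4, amplitude = 0.8, tr = 2, n_volumes = 175)
  dat <- purrr::map_dfr(1:40, function(s) {
    dplyr::mutate(gen_coupling_series(tr, seed = s), subject = s)
  })
  grp <- gbold_csf_coupling(dat, tr = 2)
  expect_equal(grp$chosen_lag, 4)
  expect_lt(mean(grp$subjects$strength), -0.6)
})

test_that("the negative-derivative check peaks positively at zero lag", {
  t <- seq(0, 348, by = 2)
  gb <- sin(2 * pi * t / 40)
  cs <- pmax(0, -cos(2 * pi * t / 40))
  nd <- neg_derivative_check(gb, cs, tr = 2)
  expect_equal(nd$lag[which.max(nd$r)], 0)
  expect_gt(max(nd$r, na.rm = TRUE), 0.9)

  # constant gBOLD: rectified derivative is identically zero, all missing
  ndc <- neg_derivative_check(rep(1, 100), rnorm(100), tr = 2)
  expect_true(all(is.na(ndc$r)))

  # rectification is idempotent
  d <- attr(nd, "derivative")
  expect_identical(pmax(0, d), d)
})

test_that("zero-variance segments yield missing correlations", {
  x <- c(rep(0, 50), rnorm(50))
  y <- rnorm(100)
  cc <- bold_csf_ccf(x, y, tr = 2, max_lag = 10)
  expect_true(all(is.finite(cc$lag)))
  expect_error(bold_csf_ccf(rnorm(10), rnorm(10), tr = 2, max_lag = 10), "short")
})

test_that("network coupling recovers per-voxel planted lags", {
  tr_s <- 2
  n_t <- 175
  base <- gen_coupling_series(
    coupling_phantom_truth(lag_true = 0, amplitude = 1, tr = tr_s, n_volumes = n_t + 4),
    seed = 5
  )
  csf_full <- base$csf
  csf <- csf_full[1:n_t]
  # voxel 1 leads the CSF series by 2 s (1 sample), voxel 2 by 4 s (2 samples)
  vb <- array(NA_real_, c(2, 1, 1, n_t))
  vb[1, 1, 1, ] <- -csf_full[2:(n_t + 1)]
  vb[2, 1, 1, ] <- -csf_full[3:(n_t + 2)]
  labels <- array(c(1L, 2L), c(2, 1, 1))
  res <- network_coupling(
    volume_grid(vb, voxel_size = c(1, 1, 1)), csf,
    volume_grid(labels), tr_s
  )
  expect_equal(res$mean_lag, c(2, 4))
  expect_equal(res$mean_strength, c(-1, -1), tolerance = 1e-10)

  # degenerate case: identical series in all voxels -> identical strengths
  vb2 <- vb
  vb2[2, 1, 1, ] <- vb[1, 1, 1, ]
  res2 <- network_coupling(volume_grid(vb2), csf, volume_grid(labels), tr_s)
  expect_equal(res2$mean_strength[1], res2$mean_strength[2])

  # permuting label IDs permutes rows only
  labels_p <- array(c(2L, 1L), c(2, 1, 1))
  res_p <- network_coupling(volume_grid(vb), csf, volume_grid(labels_p), tr_s)
  expect_equal(res_p$mean_lag[res_p$network == 1], 4)
  expect_equal(res_p$mean_lag[res_p$network == 2], 2)

  # empty requested network warns and reports NA
  expect_warning(
    res_e <- network_coupling(volume_grid(vb), csf, volume_grid(labels), tr_s,
      networks = c(1, 2, 3)
    ),
    "network 3"
  )
  expect_true(is.na(res_e$mean_strength[res_e$network == 3]))
})
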
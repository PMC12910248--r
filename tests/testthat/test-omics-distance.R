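test_that("Bray-Curtis matches hand arithmetic and its boundary cases", {
  m <- rbind(a = c(0.7, 0.3, 0), b = c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(bray_curtis(m)), 0.5)
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 2))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "b")
  expect_error(bray_curtis(rbind(c(-1, 1), c(1, 1))), "nonnegative")
})

test_that("PCoA reproduces Euclidean configurations and is permutation-stable", {
  x <- c(0, 1, 3, 7)
  d <- stats::dist(x)
  # collinear points: one dominant positive eigenvalue, fewer axes returned
  expect_warning(ord <- pcoa(d, k = 3), "positive eigenvalues")
  expect_lt(ord$eig[2] / ord$eig[1], 1e-8)
  rec <- stats::dist(ord$points$Axis.1)
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-8)

  # identical samples get identical coordinates
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 0))
  ord2 <- suppressWarnings(pcoa(stats::dist(m), k = 2))
  expect_equal(
    as.numeric(ord2$points[1, -1]),
    as.numeric(ord2$points[2, -1])
  )

  # permuting samples permutes rows only
  m3 <- withr::with_seed(4, matrix(rexp(5 * 6), 5, dimnames = list(paste0("s", 1:5), NULL)))
  perm <- c(3, 1, 5, 2, 4)
  o_a <- pcoa(bray_curtis(m3), k = 2)
  o_b <- pcoa(bray_curtis(m3[perm, ]), k = 2)
  merged <- merge(o_a$points, o_b$points, by = "sample_id")
  expect_equal(merged$Axis.1.x, merged$Axis.1.y, tolerance = 1e-10)
  expect_equal(abs(merged$Axis.2.x), abs(merged$Axis.2.y), tolerance = 1e-10)
})

test_that("PERMANOVA matches the exhaustive-enumeration oracle on small data", {
  m <- withr::with_seed(7, matrix(rexp(6 * 8), 6, dimnames = list(paste0("s", 1:6), NULL)))
  d <- bray_curtis(m)
  groups <- rep(c("a", "b"), each = 3)
  pm <- suppressMessages(permanova(d, groups, n_perm = 9999, seed = 1))
  oracle <- permanova_enum_oracle(d, 3)
  expect_equal(pm$pseudo_F, oracle$F, tolerance = 1e-10)
  # vegan enumerates completely at this size, so the p-values agree exactly
  expect_equal(pm$p_value, oracle$p, tolerance = 1e-10)
  expect_gte(pm$p_value, 1 / (pm$n_perm + 1))

  # a second instance with 8 samples
  m8 <- withr::with_seed(17, matrix(rexp(8 * 10), 8, dimnames = list(paste0("s", 1:8), NULL)))
  d8 <- bray_curtis(m8)
  pm8 <- suppressMessages(permanova(d8, rep(c("a", "b"), each = 4), n_perm = 9999, seed = 2))
  or8 <- permanova_enum_oracle(d8, 4)
  expect_equal(pm8$pseudo_F, or8$F, tolerance = 1e-10)
  expect_lt(abs(pm8$p_value - or8$p), 3 * sqrt(or8$p * (1 - or8$p) / 9999) + 1e-4)
})

test_that("PERMANOVA p-values are seed-reproducible and inputs validated", {
  m <- withr::with_seed(9, matrix(rexp(24 * 10), 24))
  d <- bray_curtis(m)
  g <- rep(c("a", "b", "c"), each = 8)
  p1 <- permanova(d, g, n_perm = 199, seed = 42)
  p2 <- permanova(d, g, n_perm = 199, seed = 42)
  expect_identical(p1$p_value, p2$p_value)
  expect_error(permanova(d, rep("a", 24), n_perm = 99), ">= 2 groups")
})

test_that("duplicating samples preserves the ordering of planted effect sizes", {
  # two planted shifts of different magnitude: pseudo-F ordering must be
  # stable under duplication of every sample
  make_f <- function(shift) {
    m <- withr::with_seed(5, matrix(rexp(20 * 12), 20))
    m[11:20, 1] <- m[11:20, 1] * shift
    g <- rep(c("a", "b"), each = 10)
    f1 <- permanova(bray_curtis(m), g, n_perm = 99, seed = 1)$pseudo_F
    m2 <- m[rep(1:20, each = 2), ]
    g2 <- rep(g, each = 2)
    f2 <- permanova(bray_curtis(m2), g2, n_perm = 99, seed = 1)$pseudo_F
    c(f1, f2)
  }
  weak <- make_f(2)
  strong <- make_f(8)
  expect_gt(strong[1], weak[1])
  expect_gt(strong[2], weak[2])
})
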
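# Shared fixtures, all generated in code.

# Engineered metabolite table: five features designed to fail exactly one
# QC rule each, five designed to pass everything. 20 subjects, 3 QC, 2 blanks.
engineered_qc_table <- function(n_sub = 20, seed = 42) {
  withr::with_seed(seed, {
    feats <- list(
      pass_1 = list(s = runif(n_sub, 80, 120), q = c(95, 100, 105), b = c(5, 5)),
      fail_ratio = list(s = runif(n_sub, 80, 120), q = c(90, 100, 110), b = c(50, 50)), # QC/blank = 2
      pass_2 = list(s = runif(n_sub, 10, 20), q = c(14, 15, 16), b = c(0.1, 0.1)),
      fail_rsd = list(s = runif(n_sub, 80, 120), q = c(50, 100, 150), b = c(5, 5)), # RSD 50%
      pass_3 = list(s = runif(n_sub, 1000, 2000), q = c(1400, 1500, 1600), b = c(10, 10)),
      fail_prev_low = list(
        s = c(rep(0, ceiling(0.55 * n_sub)), runif(n_sub - ceiling(0.55 * n_sub), 80, 120)),
        q = c(95, 100, 105), b = c(5, 5)
      ), # 45% prevalence
      pass_4 = list(s = runif(n_sub, 50, 60), q = c(54, 55, 56), b = c(2, 2)),
      fail_prev_edge = list(
        s = c(rep(0, ceiling(0.25 * n_sub)), runif(n_sub - ceiling(0.25 * n_sub), 80, 120)),
        q = c(95, 100, 105), b = c(5, 5)
      ), # 75% prevalence
      pass_5 = list(s = runif(n_sub, 5, 9), q = c(6.9, 7, 7.1), b = c(0.5, 0.5)),
      fail_constant = list(s = rep(7, n_sub), q = c(6.9, 7, 7.1), b = c(0.5, 0.5))
    )
    vals <- sapply(feats, function(f) c(f$s, f$q, f$b))
    omics_table(
      vals,
      sample_id = c(sprintf("S%02d", seq_len(n_sub)), "QC1", "QC2", "QC3", "B1", "B2"),
      role = c(rep("subject", n_sub), rep("qc", 3), rep("blank", 2)),
      group = c(rep(c("g1", "g2"), length.out = n_sub), rep(NA, 5))
    )
  })
}

# ALPS phantom ROI set on a 32 x 32 x 16 grid, spheres well separated.
phantom_alps_rois <- function() {
  alps_rois(
    centers = rbind(
      left_scr = c(6, 16, 8),
      left_slf = c(12, 16, 8),
      right_scr = c(26, 16, 8),
      right_slf = c(20, 16, 8)
    ),
    diameter_mm = 5, space = "phantom-32x32x16"
  )
}

const_vol <- function(v, shape = c(32, 32, 16)) volume_grid(array(v, shape))

# Paint ROI-sphere values into per-axis diffusivity maps for the hand-computed
# ALPS case: Dxx proj/assoc = 1.2/1.0, Dyy proj = 0.7, Dzz assoc = 0.6 (x1e-3).
painted_alps_maps <- function() {
  shape <- c(32, 32, 16)
  rois <- phantom_alps_rois()
  base <- function() array(1e-3, shape)
  vg0 <- const_vol(0, shape)
  paint <- function(arr, roi, val) {
    m <- glymphomics:::sphere_mask(vg0, rois$centers[roi, ], rois$diameter_mm / 2)
    arr[m] <- val
    arr
  }
  dxx <- base()
  for (r in c("left_scr", "right_scr")) dxx <- paint(dxx, r, 1.2e-3)
  for (r in c("left_slf", "right_slf")) dxx <- paint(dxx, r, 1.0e-3)
  dyy <- base()
  for (r in c("left_scr", "right_scr")) dyy <- paint(dyy, r, 0.7e-3)
  dzz <- base()
  for (r in c("left_slf", "right_slf")) dzz <- paint(dzz, r, 0.6e-3)
  list(
    dxx = volume_grid(dxx), dyy = volume_grid(dyy), dzz = volume_grid(dzz),
    rois = rois
  )
}

# Corpus-callosum-like tissue tensor: strongly anisotropic, MD ~ 0.77e-3.
cc_tensor <- function() diag(c(1.8e-3, 0.25e-3, 0.25e-3))

# Exhaustive-enumeration PERMANOVA oracle for two groups (first `n1` samples
# vs the rest), written directly from the squared-distance partition.
permanova_enum_oracle <- function(d, n1) {
  Dm <- as.matrix(d)
  n <- nrow(Dm)
  pseudo_f <- function(idx1) {
    sst <- sum(Dm^2) / (2 * n)
    ssw <- sum(Dm[idx1, idx1]^2) / (2 * length(idx1)) +
      sum(Dm[-idx1, -idx1]^2) / (2 * (n - length(idx1)))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f0 <- pseudo_f(seq_len(n1))
  combs <- utils::combn(n, n1)
  fs <- apply(combs, 2, pseudo_f)
  list(F = f0, p = mean(fs >= f0 - 1e-12))
}
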
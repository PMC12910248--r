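#' Frangi filter parameters
#'
#' Multiscale Hessian vesselness parameters. Defaults follow the original
#' recommendations: plate/blob sensitivities alpha = beta = 0.5, the
#' structureness constant c set per scale to half the maximum Hessian
#' Frobenius norm, scales spanning 0.1 to 5 voxels, and a vesselness
#' threshold of 2e-5 for perivascular-space segmentation.
#'
#' @param scales_vox Increasing positive Gaussian scales in voxel units.
#' @param alpha,beta Sensitivity constants for the plate- and blob-rejection
#'   terms.
#' @param c Structureness constant, or `"auto"` for half the per-scale
#'   maximum Frobenius norm.
#' @param threshold Vesselness cutoff used by [segment_pvs()].
#' @return An object of class `frangi_params`.
#' @export
frangi_params <- function(scales_vox = c(0.1, 0.5, 1, 2, 3, 4, 5),
                          alpha = 0.5, beta = 0.5, c = "auto",
                          threshold = 2e-5) {
  scales_vox <- as.numeric(scales_vox)
  if (any(scales_vox <= 0) || is.unsorted(scales_vox, strictly = TRUE)) {
    abort("`scales_vox` must be positive and strictly increasing.")
  }
  check_scalar(alpha, "alpha", positive = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  if (!identical(c, "auto")) check_scalar(c, "c", positive = TRUE)
  check_scalar(threshold, "threshold", positive = TRUE)
  structure(
    list(
      scales_vox = scales_vox, alpha = alpha, beta = beta, c = c,
      threshold = threshold
    ),
    class = "frangi_params"
  )
}

# Sampled Gaussian kernel and its first/second derivatives at scale sigma
# (voxels). Moment-corrected so that constants and linear ramps respond with
# exactly zero derivative under replicate-edge padding.
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  g1 <- g1 - mean(g1) # zero-sum
  s1 <- sum(-x * g1)
  if (s1 > 0) g1 <- g1 / s1 # unit response on ramps
  g2 <- (x^2 / sigma^2 - 1) / sigma^2 * exp(-x^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)
  s2 <- sum(x^2 / 2 * g2)
  if (s2 > 0) g2 <- g2 / s2 # unit response on quadratics
  list(g = g, g1 = g1, g2 = g2)
}

# Convolve a 3-D array along one axis with replicate-edge padding, via a
# banded matrix multiply.
conv_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (t in -r:r) {
    src <- pmin(pmax(seq_len(n) + t, 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[t + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(vol, perm), nrow = n)
  out <- K %*% m
  aperm(array(out, d[perm]), order(perm))
}

# Separable filtering: orders[i] in {0,1,2} selects g, g', g'' along axis i.
gauss_filter3 <- function(vol, sigma, orders) {
  k <- gauss_kernels(sigma)
  pick <- list(k$g, k$g1, k$g2)
  for (ax in 1:3) {
    vol <- conv_axis(vol, pick[[orders[ax] + 1L]], ax)
  }
  vol
}

# Vectorized eigenvalues of symmetric 3x3 fields (trigonometric closed form).
# Inputs are arrays of the six components; returns a list lam1, lam2, lam3
# sorted by increasing |lambda|.
sym33_eigenvalues <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- pmax(p, .Machine$double.eps)
  bxx <- (xx - q) / safe_p
  byy <- (yy - q) / safe_p
  bzz <- (zz - q) / safe_p
  bxy <- xy / safe_p
  bxz <- xz / safe_p
  byz <- yz / safe_p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  iso <- p < .Machine$double.eps
  e1[iso] <- q[iso]
  e2[iso] <- q[iso]
  e3[iso] <- q[iso]
  # sort by |lambda| per voxel
  E <- cbind(as.vector(e1), as.vector(e2), as.vector(e3))
  A <- abs(E)
  o1 <- max.col(-A, ties.method = "first")
  o3 <- max.col(A, ties.method = "last")
  same <- o1 == o3 # all equal magnitudes
  o3[same] <- (o3[same] %% 3) + 1
  o2 <- 6 - o1 - o3
  n <- nrow(E)
  list(
    l1 = E[cbind(seq_len(n), o1)],
    l2 = E[cbind(seq_len(n), o2)],
    l3 = E[cbind(seq_len(n), o3)]
  )
}

#' Multiscale Frangi vesselness
#'
#' Hessian-eigenvalue vesselness for bright tubular structures on a dark
#' background, taking the maximum response across Gaussian scales. With
#' eigenvalues sorted by magnitude (|l1| <= |l2| <= |l3|) the per-scale
#' response is
#' \deqn{(1 - e^{-R_A^2 / 2\alpha^2}) e^{-R_B^2 / 2\beta^2} (1 - e^{-S^2 / 2c^2})}
#' with R_A = |l2|/|l3| (plate rejection), R_B = |l1|/sqrt(|l2 l3|) (blob
#' rejection), and structureness S the Hessian Frobenius norm; the response
#' is zero wherever l2 > 0 or l3 > 0. Second derivatives are
#' scale-normalized (multiplied by sigma^2). Scales are interpreted in voxel
#' units; a warning is issued for anisotropic voxels.
#'
#' @param vol 3-D [volume_grid()].
#' @param params A [frangi_params()].
#' @return A [volume_grid()] of vesselness in `[0, 1]`.
#' @export
frangi_vesselness <- function(vol, params = frangi_params()) {
  if (!inherits(vol, "volume_grid") || length(dim(vol$data)) != 3) {
    abort("`vol` must be a 3-D volume_grid.")
  }
  if (!inherits(params, "frangi_params")) abort("`params` must be frangi_params.")
  if (diff(range(vol$voxel_size)) > 1e-6 * max(vol$voxel_size)) {
    warn("anisotropic voxels: Frangi scales are interpreted in voxel units.")
  }
  x <- vol$data
  best <- array(0, dim(x))
  for (s in params$scales_vox) {
    hxx <- s^2 * gauss_filter3(x, s, c(2, 0, 0))
    hyy <- s^2 * gauss_filter3(x, s, c(0, 2, 0))
    hzz <- s^2 * gauss_filter3(x, s, c(0, 0, 2))
    hxy <- s^2 * gauss_filter3(x, s, c(1, 1, 0))
    hxz <- s^2 * gauss_filter3(x, s, c(1, 0, 1))
    hyz <- s^2 * gauss_filter3(x, s, c(0, 1, 1))
    ev <- sym33_eigenvalues(hxx, hyy, hzz, hxy, hxz, hyz)
    S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
    # a (shifted) constant volume has zero Hessian up to rounding noise
    s_ref <- diff(range(x))
    if (s_ref == 0 || sqrt(max(S2)) <= 1e-8 * s_ref) next
    if (identical(params$c, "auto")) {
      cc <- 0.5 * sqrt(max(S2))
    } else {
      cc <- params$c
    }
    a2 <- abs(ev$l2)
    a3 <- abs(ev$l3)
    ra2 <- (a2 / pmax(a3, .Machine$double.xmin))^2
    rb2 <- ev$l1^2 / pmax(a2 * a3, .Machine$double.xmin)
    v <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
      exp(-rb2 / (2 * params$beta^2)) *
      (1 - exp(-S2 / (2 * cc^2)))
    v[ev$l2 > 0 | ev$l3 > 0] <- 0
    v[a3 <= 0] <- 0
    best <- pmax(best, array(v, dim(x)))
  }
  volume_grid(best, vol$voxel_size, vol$affine)
}

#' Segment perivascular spaces and compute their volume fraction
#'
#' Thresholds the vesselness map at the optimized cutoff, restricts the
#' result to the basal-ganglia label mask, and reports the PVS volume
#' fraction: segmented volume (voxel count x voxel volume) divided by the
#' intracranial volume.
#'
#' @param vesselness [volume_grid()] from [frangi_vesselness()].
#' @param params A [frangi_params()] (supplies the threshold).
#' @param bg_labels [volume_grid()] whose positive voxels delimit the basal
#'   ganglia (or any target region), on the same grid.
#' @param icv_mm3 Intracranial volume in mm^3 (> 0).
#' @return A list: `mask` (logical array), `pvsvf` (volume fraction),
#'   `n_voxels`, `volume_mm3`.
#' @export
segment_pvs <- function(vesselness, params, bg_labels, icv_mm3) {
  if (!inherits(vesselness, "volume_grid")) {
    abort("`vesselness` must be a volume_grid.")
  }
  check_scalar(icv_mm3, "icv_mm3", positive = TRUE)
  check_same_grid(vesselness, bg_labels, "vesselness and label volumes")
  mask <- vesselness$data >= params$threshold & bg_labels$data > 0
  vol_mm3 <- sum(mask) * voxel_volume(vesselness)
  list(
    mask = mask,
    pvsvf = vol_mm3 / icv_mm3,
    n_voxels = sum(mask),
    volume_mm3 = vol_mm3
  )
}
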
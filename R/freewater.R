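#' Fit the single-shell two-compartment free-water model
#'
#' Per masked voxel, estimates the free-water fraction f in `[0, 1]` and a
#' free-water-corrected tissue tensor D by minimizing the signal-space
#' residual between the measured single-shell signal and
#' \deqn{S_0 [ f e^{-b d_{iso}} + (1 - f) e^{-b g^T D g} ]}
#' with the isotropic diffusivity fixed at `d_iso` (water at body
#' temperature) and S0 estimated from the b = 0 volumes, shared by both
#' compartments (this shared amplitude is what identifies f on a single
#' shell). The fit initializes with a coarse grid over f, profiling the
#' tensor at each candidate by a weighted log-linear fit of the tissue
#' signal, then refines f by bounded one-dimensional optimization around
#' the best grid point. No spatial regularization is applied.
#'
#' @param dwi 4-D [volume_grid()] (x, y, z, volume).
#' @param gtab Single-shell [gradient_table()] with >= 6 directions.
#' @param mask Optional logical 3-D array or [volume_grid()]; default all
#'   voxels.
#' @param f_grid Grid of candidate free-water fractions for initialization.
#' @param d_iso Free-water diffusivity in mm^2/s.
#' @param refine Run the bounded 1-D refinement after the grid stage.
#' @param regularize Apply spatial regularization before the voxel-wise fit:
#'   the noise level is estimated from the b = 0 repeats, the squared
#'   magnitudes are Rician-corrected (E\[m^2\] = S^2 + 2 sigma^2), and the
#'   corrected squared signal is pooled spatially. Per-voxel single-shell
#'   free-water estimation is weakly identified at realistic SNR (the
#'   Cramer-Rao bound on f is of order 1), so noisy data require pooling.
#' @param reg_sigma_vox Gaussian pooling scale in voxels; `Inf` (default)
#'   pools over the whole mask, appropriate for a homogeneous region.
#' @return An object of class `fw_fit` with elements `fw` (3-D
#'   [volume_grid()], NA outside the mask), `tensor` (4-D grid of the six
#'   tensor components xx, yy, zz, xy, xz, yz with eigenvalues clipped to
#'   >= 0), `rss` (per-voxel residual sum of squares), `converged`, `d_iso`.
#' @export
fit_free_water <- function(dwi, gtab, mask = NULL,
                           f_grid = seq(0, 1, by = 0.05),
                           d_iso = 3.0e-3, refine = TRUE,
                           regularize = FALSE, reg_sigma_vox = Inf) {
  if (!inherits(dwi, "volume_grid") || length(dim(dwi$data)) != 4) {
    abort("`dwi` must be a 4-D volume_grid.")
  }
  assert_single_shell(gtab)
  shape <- dim(dwi$data)[1:3]
  nb <- dim(dwi$data)[4]
  if (nb != length(gtab$bvals)) {
    abort("number of volumes does not match the gradient table.")
  }
  if (is.null(mask)) {
    mask <- array(TRUE, shape)
  } else {
    if (inherits(mask, "volume_grid")) mask <- mask$data
    mask <- array(as.logical(mask > 0), shape)
  }
  if (!any(mask)) abort("`mask` is empty.")

  b <- gtab$bvals
  g <- gtab$bvecs
  if (regularize) {
    dwi <- fw_regularize_signal(dwi, mask, b, reg_sigma_vox)
  }
  S <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = nb)
  S <- t(S)[as.vector(mask), , drop = FALSE] # voxels x volumes
  n_mask <- nrow(S)
  # mask-wide pooling leaves one distinct signal: fit it once, broadcast
  pooled_fit <- regularize && is.infinite(reg_sigma_vox)
  if (pooled_fit) S <- S[1, , drop = FALSE]
  s0 <- rowMeans(S[, b <= 0, drop = FALSE])
  ok <- is.finite(s0) & s0 > 0 & rowSums(!is.finite(S)) == 0
  atten_iso <- exp(-b * d_iso)

  # tissue tensor design (no intercept: the amplitude is tied to (1-f) S0):
  # log(S_tissue / ((1-f) S0)) = -b g^T D g
  Xq <- cbind(
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3]
  )
  Pq <- solve(crossprod(Xq), t(Xq)) # unweighted pseudo-inverse, 6 x nb

  nv <- nrow(S)
  fw <- rep(NA_real_, nv)
  rss <- rep(NA_real_, nv)
  beta_best <- matrix(NA_real_, nv, 6)

  vox <- which(ok)
  if (length(vox) > 0) {
    Sv <- S[vox, , drop = FALSE]
    s0v <- s0[vox]
    floor_v <- pmax(s0v * 1e-6, 1e-12)
    best_rss <- rep(Inf, length(vox))
    best_f <- rep(0, length(vox))
    best_beta <- matrix(0, length(vox), 6)
    for (f in f_grid) {
      iso_part <- (f * s0v) %o% atten_iso
      if (1 - f < 1e-8) {
        shat <- iso_part
        beta <- matrix(0, length(vox), 6)
      } else {
        A <- pmax(Sv - iso_part, floor_v)
        resp <- log(A) - log((1 - f) * s0v)
        beta <- resp %*% t(Pq)
        shat <- iso_part + ((1 - f) * s0v) * exp(beta %*% t(Xq))
      }
      r <- rowSums((Sv - shat)^2)
      upd <- r < best_rss
      best_rss[upd] <- r[upd]
      best_f[upd] <- f
      best_beta[upd, ] <- beta[upd, , drop = FALSE]
    }
    if (refine) {
      step <- if (length(f_grid) > 1) max(diff(sort(f_grid))) else 0.05
      for (i in seq_along(vox)) {
        sv <- Sv[i, ]
        lo <- max(0, best_f[i] - step)
        hi <- min(1, best_f[i] + step)
        obj <- function(f) {
          fw_profile_fit(f, sv, s0v[i], atten_iso, Xq, floor_v[i])$rss
        }
        opt <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
        cand <- fw_profile_fit(opt$minimum, sv, s0v[i], atten_iso, Xq, floor_v[i])
        if (cand$rss <= best_rss[i]) {
          best_rss[i] <- cand$rss
          best_f[i] <- opt$minimum
          best_beta[i, ] <- cand$beta
        }
      }
    }
    fw[vox] <- pmin(1, pmax(0, best_f))
    rss[vox] <- best_rss
    beta_best[vox, ] <- best_beta
  }

  # tensors with eigenvalues clipped to >= 0
  tensor6 <- matrix(NA_real_, nv, 6)
  for (i in vox) {
    D <- matrix(
      c(
        beta_best[i, 1], beta_best[i, 4], beta_best[i, 5],
        beta_best[i, 4], beta_best[i, 2], beta_best[i, 6],
        beta_best[i, 5], beta_best[i, 6], beta_best[i, 3]
      ), 3, 3
    )
    e <- eigen(D, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    Dc <- e$vectors %*% (lam * t(e$vectors))
    tensor6[i, ] <- c(Dc[1, 1], Dc[2, 2], Dc[3, 3], Dc[1, 2], Dc[1, 3], Dc[2, 3])
  }

  if (pooled_fit) {
    fw <- rep(fw, n_mask)
    rss <- rep(rss, n_mask)
    tensor6 <- tensor6[rep(1L, n_mask), , drop = FALSE]
    ok <- rep(ok, n_mask)
  }
  expand <- function(v) {
    out <- array(NA_real_, shape)
    out[mask] <- v
    out
  }
  tens <- array(NA_real_, c(shape, 6))
  for (j in 1:6) tens[, , , j][mask] <- tensor6[, j]
  conv <- array(FALSE, shape)
  conv[mask] <- ok

  structure(
    list(
      fw = volume_grid(expand(fw), dwi$voxel_size, dwi$affine),
      tensor = volume_grid(tens, dwi$voxel_size, dwi$affine),
      rss = expand(rss),
      converged = conv,
      d_iso = d_iso,
      mask = mask
    ),
    class = "fw_fit"
  )
}

# Rician second-moment correction and spatial pooling of the DWI signal.
# sigma^2 is estimated from the b = 0 repeats (pooled over the mask);
# corrected squared magnitudes (E[m^2] - 2 sigma^2) are pooled with a
# Gaussian of `sigma_vox` voxels, or averaged over the whole mask when
# `sigma_vox` is infinite.
fw_regularize_signal <- function(dwi, mask, b, sigma_vox) {
  nb <- length(b)
  b0_idx <- which(b <= 0)
  sigma2 <- 0
  if (length(b0_idx) >= 2) {
    b0 <- matrix(dwi$data[, , , b0_idx, drop = FALSE], ncol = length(b0_idx))
    b0 <- b0[as.vector(mask), , drop = FALSE]
    sigma2 <- mean(apply(b0, 1, var))
  }
  out <- dwi
  if (is.infinite(sigma_vox)) {
    M <- matrix(dwi$data, ncol = nb)
    pooled <- sqrt(pmax(colMeans(M[as.vector(mask), , drop = FALSE]^2) - 2 * sigma2, 0))
    for (j in seq_len(nb)) {
      v <- out$data[, , , j]
      v[mask] <- pooled[j]
      out$data[, , , j] <- v
    }
  } else {
    k <- gauss_kernels(sigma_vox)$g
    for (j in seq_len(nb)) {
      v <- pmax(dwi$data[, , , j]^2 - 2 * sigma2, 0)
      for (ax in 1:3) v <- conv_axis(v, k, ax)
      out$data[, , , j] <- sqrt(pmax(v, 0))
    }
  }
  out
}

# Profile objective: given f, fit the tissue tensor (amplitude tied to
# (1 - f) S0) by a weighted log-linear fit (weights ~ signal^2, the
# delta-method weighting for log-domain least squares) and return the
# signal-space residual sum of squares.
fw_profile_fit <- function(f, sv, s0i, atten_iso, Xq, floor_i) {
  iso_part <- f * s0i * atten_iso
  if (1 - f < 1e-8) {
    return(list(rss = sum((sv - iso_part)^2), beta = rep(0, 6)))
  }
  A <- pmax(sv - iso_part, floor_i)
  resp <- log(A) - log((1 - f) * s0i)
  w <- A^2
  XtW <- t(Xq * w)
  beta <- tryCatch(
    solve(XtW %*% Xq, XtW %*% resp),
    error = function(e) solve(crossprod(Xq), crossprod(Xq, resp))
  )
  shat <- iso_part + (1 - f) * s0i * exp(drop(Xq %*% beta))
  list(rss = sum((sv - shat)^2), beta = drop(beta))
}

#' @export
print.fw_fit <- function(x, ...) {
  v <- x$fw$data[x$converged]
  cat(sprintf(
    "<fw_fit> %d fitted voxels; FW mean %.3f (range %.3f-%.3f); d_iso %.2g mm^2/s\n",
    length(v), mean(v), min(v), max(v), x$d_iso
  ))
  invisible(x)
}

#' Mean free-water fraction within white matter, excluding PVS
#'
#' Averages the fitted free-water map over the white-matter mask minus the
#' perivascular-space mask, counting only converged voxels.
#'
#' @param fw An [fit_free_water()] result, or a 3-D [volume_grid()] of
#'   free-water fractions.
#' @param wm_mask White-matter mask (logical array or [volume_grid()]).
#' @param pvs_mask Optional perivascular-space mask to exclude.
#' @return A one-row tibble with `mean_fw` and `n_voxels`.
#' @export
mean_fw_wm <- function(fw, wm_mask, pvs_mask = NULL) {
  if (inherits(fw, "fw_fit")) {
    map <- fw$fw$data
    conv <- fw$converged
  } else if (inherits(fw, "volume_grid")) {
    map <- fw$data
    conv <- array(TRUE, dim(map))
  } else {
    abort("`fw` must be an fw_fit or a volume_grid.")
  }
  as_mask <- function(m) {
    if (is.null(m)) {
      return(NULL)
    }
    if (inherits(m, "volume_grid")) m <- m$data
    array(as.logical(m > 0), dim(map))
  }
  wm <- as_mask(wm_mask)
  pvs <- as_mask(pvs_mask)
  eff <- wm & conv & is.finite(map)
  if (!is.null(pvs)) eff <- eff & !pvs
  if (!any(eff)) {
    abort("empty effective mask: no white-matter voxels left after exclusions.")
  }
  tibble(mean_fw = mean(map[eff]), n_voxels = sum(eff))
}
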
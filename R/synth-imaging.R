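#' Planted ground truth for a single-shell DWI phantom
#'
#' @param fw_field Free-water fraction per voxel: a 3-D array in `[0, 1]`, or
#'   a scalar recycled over the grid at generation time.
#' @param tissue_tensor Symmetric positive semi-definite 3x3 diffusion tensor
#'   (mm^2/s) of the tissue compartment.
#' @param snr Rician signal-to-noise ratio at b = 0, or `NULL` for a
#'   noiseless phantom.
#' @param d_iso Isotropic diffusivity of free water; fixed by physiology at
#'   3.0e-3 mm^2/s (water at body temperature).
#' @param s0 Non-diffusion-weighted signal level.
#' @return An object of class `dwi_phantom_truth`.
#' @export
dwi_phantom_truth <- function(fw_field, tissue_tensor, snr = NULL,
                              d_iso = 3.0e-3, s0 = 1000) {
  if (any(fw_field < 0 | fw_field > 1, na.rm = TRUE)) {
    abort("`fw_field` must lie in [0, 1].")
  }
  tissue_tensor <- as.matrix(tissue_tensor)
  if (!all(dim(tissue_tensor) == c(3, 3)) ||
    max(abs(tissue_tensor - t(tissue_tensor))) > 1e-12) {
    abort("`tissue_tensor` must be a symmetric 3x3 matrix.")
  }
  if (min(eigen(tissue_tensor, symmetric = TRUE, only.values = TRUE)$values) <
    -1e-12) {
    abort("`tissue_tensor` must be positive semi-definite.")
  }
  if (!is.null(snr)) check_scalar(snr, "snr", positive = TRUE)
  check_scalar(d_iso, "d_iso", positive = TRUE)
  check_scalar(s0, "s0", positive = TRUE)
  structure(
    list(
      fw_field = fw_field, tissue_tensor = tissue_tensor, snr = snr,
      d_iso = d_iso, s0 = s0
    ),
    class = "dwi_phantom_truth"
  )
}

#' Generate a single-shell DWI phantom with a planted free-water compartment
#'
#' Per voxel, the noiseless signal follows the two-compartment model
#' \deqn{S(b, g) = S_0 [ f e^{-b d_{iso}} + (1 - f) e^{-b g^T D g} ]}
#' with the planted free-water fraction f and tissue tensor D. When the truth
#' specifies an SNR, Rician noise is applied as the magnitude of the signal
#' plus complex Gaussian noise of SD `s0 / snr` per channel.
#'
#' @param truth A [dwi_phantom_truth()].
#' @param shape Length-3 integer grid size.
#' @param gtab A single-shell [gradient_table()] with >= 6 directions.
#' @param voxel_size Voxel dimensions in mm.
#' @param seed Seed for the noise stream (ignored for noiseless phantoms).
#' @return A 4-D [volume_grid()] (x, y, z, volume) with the truth attached as
#'   attribute `"truth"`.
#' @export
gen_dwi_phantom <- function(truth, shape, gtab, voxel_size = c(2, 2, 2),
                            seed = 1L) {
  if (!inherits(truth, "dwi_phantom_truth")) {
    abort("`truth` must be a dwi_phantom_truth.")
  }
  b <- assert_single_shell(gtab)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) abort("`shape` must be 3 sizes.")
  nvox <- prod(shape)
  f <- truth$fw_field
  if (length(f) == 1) f <- array(f, shape)
  if (!all(dim(f) == shape)) abort("`fw_field` does not match `shape`.")
  D <- truth$tissue_tensor
  g <- gtab$bvecs
  q <- rowSums((g %*% D) * g) # g^T D g per volume
  atten_tissue <- exp(-gtab$bvals * q)
  atten_iso <- exp(-gtab$bvals * truth$d_iso)
  fv <- as.vector(f)
  signal <- truth$s0 * (outer(fv, atten_iso) + outer(1 - fv, atten_tissue))
  if (!is.null(truth$snr)) {
    sigma <- truth$s0 / truth$snr
    signal <- with_local_seed(seed, {
      sqrt((signal + rnorm(length(signal), sd = sigma))^2 +
        rnorm(length(signal), sd = sigma)^2)
    })
  }
  vol <- array(signal, c(shape, length(gtab$bvals)))
  out <- volume_grid(vol, voxel_size = voxel_size)
  attr(out, "truth") <- truth
  out
}

#' Planted ground truth for a BOLD-CSF coupling phantom
#'
#' @param lag_true Planted lag in seconds (positive = the CSF series follows
#'   the global BOLD series); |lag| <= 10 s.
#' @param amplitude Target magnitude of the population cross-correlation peak,
#'   in `[0, 1]`.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of time points (>= 50).
#' @return An object of class `coupling_phantom_truth`.
#' @export
coupling_phantom_truth <- function(lag_true = 4, amplitude = 0.8, tr = 2,
                                   n_volumes = 175) {
  check_scalar(tr, "tr", positive = TRUE)
  check_scalar(lag_true, "lag_true")
  if (abs(lag_true) > 10) abort("|lag_true| must be <= 10 s.")
  if (amplitude < 0 || amplitude > 1) abort("`amplitude` must be in [0, 1].")
  if (n_volumes < 50) abort("`n_volumes` must be >= 50.")
  structure(
    list(
      lag_true = lag_true, amplitude = amplitude, tr = tr,
      n_volumes = as.integer(n_volumes)
    ),
    class = "coupling_phantom_truth"
  )
}

# Band-limited (0.01-0.1 Hz) unit-variance Gaussian series of length n at TR.
bandlimited_noise <- function(n, tr, f_lo = 0.01, f_hi = 0.1) {
  x <- rnorm(n)
  freq <- c(0, seq_len(n - 1)) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq) # two-sided frequency axis
  keep <- freq >= f_lo & freq <= f_hi
  if (!any(keep)) abort("series too short for the 0.01-0.1 Hz passband.")
  xf <- stats::fft(x)
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  as.numeric(scale(y))
}

#' Generate a paired gBOLD / CSF series with a planted negative coupling
#'
#' The global BOLD series is band-limited (0.01-0.1 Hz) Gaussian noise; the
#' CSF series is its negatively scaled copy shifted by the planted lag, plus
#' independent band-limited noise calibrated so the population
#' cross-correlation peak magnitude equals the truth's `amplitude`. Lags that
#' are not multiples of TR are rounded to the nearest sample (reported in
#' attribute `"lag_used"` and by a message).
#'
#' @param truth A [coupling_phantom_truth()].
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `gbold`, `csf`; attributes `"truth"`
#'   and `"lag_used"`.
#' @export
gen_coupling_series <- function(truth, seed = 1L) {
  if (!inherits(truth, "coupling_phantom_truth")) {
    abort("`truth` must be a coupling_phantom_truth.")
  }
  k <- round(truth$lag_true / truth$tr)
  lag_used <- k * truth$tr
  if (abs(lag_used - truth$lag_true) > 1e-9) {
    inform(sprintf(
      "lag_true %.3g s is not a multiple of TR; rounded to %.3g s.",
      truth$lag_true, lag_used
    ))
  }
  n <- truth$n_volumes
  pad <- abs(k)
  with_local_seed(seed, {
    base <- bandlimited_noise(n + 2 * pad + 16, truth$tr)
    start <- pad + 8
    gbold <- base[(start + 1):(start + n)]
    shifted <- base[(start + 1 - k):(start + n - k)] # csf follows gbold by k
    a <- truth$amplitude
    if (a == 0) {
      csf <- bandlimited_noise(n, truth$tr)
    } else if (a >= 1) {
      csf <- -shifted
    } else {
      noise <- bandlimited_noise(n, truth$tr)
      csf <- -shifted + sqrt(1 / a^2 - 1) * noise
    }
    out <- tibble(
      time = (seq_len(n) - 1) * truth$tr,
      gbold = as.numeric(scale(gbold)),
      csf = as.numeric(scale(csf))
    )
    attr(out, "truth") <- truth
    attr(out, "lag_used") <- lag_used
    out
  })
}

#' Generate a tube phantom for vesselness testing
#'
#' Bright cylinders of the requested radii at random, non-overlapping
#' positions and orientations on a dark background, with an exact truth mask
#' of tube voxels. Emulates perivascular spaces as tubular bright structures.
#'
#' @param shape Length-3 grid size (voxels).
#' @param radii_mm Tube radii in mm (one tube per entry).
#' @param noise_sd Additive Gaussian intensity noise SD (0 = noiseless).
#' @param voxel_size Voxel dimensions in mm (isotropic recommended).
#' @param intensity Tube intensity above the zero background.
#' @param length_frac Tube length as a fraction of the smallest grid extent.
#' @param max_retries Placement retries per tube before giving up.
#' @param seed Integer seed.
#' @return A list: `volume` ([volume_grid()]), `mask` (logical array of true
#'   tube voxels), and `tubes` (tibble of centers, axes, radii).
#' @export
gen_tube_phantom <- function(shape, radii_mm, noise_sd = 0,
                             voxel_size = c(1, 1, 1), intensity = 1,
                             length_frac = 0.6, max_retries = 50, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3) abort("`shape` must be 3 sizes.")
  if (any(radii_mm <= 0)) abort("radii must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  idx <- as.matrix(expand.grid(
    x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3])
  ))
  world <- sweep(idx - 1, 2, voxel_size, `*`)
  extent <- (shape - 1) * voxel_size
  half_len <- length_frac * min(extent) / 2
  mask <- array(FALSE, shape)
  tubes <- list()
  with_local_seed(seed, {
    for (r in radii_mm) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        centre <- runif(3, 0.25, 0.75) * extent
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        rel <- sweep(world, 2, centre)
        along <- drop(rel %*% u)
        radial2 <- rowSums(rel^2) - along^2
        vox <- radial2 <= r^2 & abs(along) <= half_len
        cand <- array(vox, shape)
        if (!any(cand & mask)) {
          mask <- mask | cand
          tubes[[length(tubes) + 1]] <- tibble(
            cx = centre[1], cy = centre[2], cz = centre[3],
            ux = u[1], uy = u[2], uz = u[3], radius_mm = r
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place a radius-%g tube without overlap after %d retries.",
          r, max_retries
        ))
      }
    }
    vol <- array(0, shape)
    vol[mask] <- intensity
    if (noise_sd > 0) vol <- vol + array(rnorm(prod(shape), sd = noise_sd), shape)
    list(
      volume = volume_grid(vol, voxel_size = voxel_size),
      mask = mask,
      tubes = dplyr::bind_rows(tubes)
    )
  })
}
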
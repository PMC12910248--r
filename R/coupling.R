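# Lag grid in samples for a symmetric window of max_lag seconds at TR.
lag_grid_samples <- function(tr, max_lag) {
  kmax <- floor(max_lag / tr + 1e-9)
  (-kmax):kmax
}

# Pearson correlation of the overlapping segments at a lag of k samples
# (k > 0: the second series follows the first). NA when the overlap is too
# short or either segment has zero variance.
cor_at_lag <- function(a, b, k, min_overlap = 30) {
  n <- length(a)
  if (k >= 0) {
    ia <- seq_len(n - k)
    ib <- ia + k
  } else {
    ib <- seq_len(n + k)
    ia <- ib - k
  }
  if (length(ia) < min_overlap) {
    return(NA_real_)
  }
  sa <- a[ia]
  sb <- b[ib]
  if (sd(sa) == 0 || sd(sb) == 0) {
    return(NA_real_)
  }
  cor(sa, sb)
}

# Tie-break for the most negative ccf: smaller |lag| first, then positive lag.
argmin_lag <- function(lags, r) {
  ok <- which(is.finite(r))
  if (length(ok) == 0) {
    return(NA_real_)
  }
  rmin <- min(r[ok])
  cand <- lags[ok][r[ok] <= rmin + 1e-15]
  cand[order(abs(cand), -sign(cand))][1]
}

#' Cross-correlation function between gBOLD and CSF series
#'
#' Pearson correlation of the overlapping, lag-shifted segments at every
#' integer multiple of TR within `[-max_lag, +max_lag]`. Positive lags mean
#' the CSF series follows the global BOLD series. The per-series
#' `chosen_lag` is the lag of the most negative correlation (ties broken
#' toward smaller |lag|, then positive lag); group-level lag selection
#' across subjects is done by [gbold_csf_coupling()].
#'
#' @param gbold,csf Equal-length numeric series.
#' @param tr Repetition time in seconds.
#' @param max_lag Maximum |lag| in seconds (default 10).
#' @param min_overlap Minimum overlapping samples for a defined correlation.
#' @return A tibble of class `coupling_ccf` with columns `lag` (s) and `r`,
#'   and attributes `chosen_lag` and `strength` (r at the chosen lag).
#' @export
#' @examples
#' x <- sin(seq(0, 20, by = 0.25))
#' bold_csf_ccf(x, -x, tr = 2)
bold_csf_ccf <- function(gbold, csf, tr, max_lag = 10, min_overlap = 30) {
  check_scalar(tr, "tr", positive = TRUE)
  if (length(gbold) != length(csf)) abort("series must have equal length.")
  if (length(gbold) <= 2 * max_lag / tr) {
    abort("series too short for the requested lag range.")
  }
  ks <- lag_grid_samples(tr, max_lag)
  r <- vapply(ks, function(k) cor_at_lag(gbold, csf, k, min_overlap), 0)
  out <- tibble(lag = ks * tr, r = r)
  chosen <- argmin_lag(out$lag, out$r)
  attr(out, "tr") <- tr
  attr(out, "chosen_lag") <- chosen
  attr(out, "strength") <- if (is.na(chosen)) NA_real_ else out$r[out$lag == chosen]
  class(out) <- c("coupling_ccf", class(out))
  out
}

#' Group-level gBOLD-CSF coupling strength
#'
#' Computes each subject's cross-correlation function, averages it across
#' subjects, fixes the group lag at the most negative mean correlation, and
#' reports each subject's coupling strength as their correlation at that
#' fixed lag (the group-level convention for this marker).
#'
#' @param data Long tibble with one row per subject and time point.
#' @param subject,gbold,csf Column names (strings) in `data`.
#' @param tr Repetition time in seconds.
#' @param max_lag Maximum |lag| in seconds.
#' @return A list of class `coupling_group`: `chosen_lag`, `mean_ccf`
#'   (tibble lag/r), and `subjects` (tibble subject/strength).
#' @export
gbold_csf_coupling <- function(data, subject = "subject", gbold = "gbold",
                               csf = "csf", tr = 2, max_lag = 10) {
  ids <- pull_col(data, subject)
  ccfs <- lapply(split(seq_len(nrow(data)), ids), function(rows) {
    bold_csf_ccf(data[[gbold]][rows], data[[csf]][rows], tr, max_lag)
  })
  rmat <- vapply(ccfs, function(cc) cc$r, ccfs[[1]]$r)
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  lags <- ccfs[[1]]$lag
  chosen <- argmin_lag(lags, mean_r)
  strengths <- rmat[which(lags == chosen), ]
  structure(
    list(
      chosen_lag = chosen,
      mean_ccf = tibble(lag = lags, r = mean_r),
      subjects = tibble(subject = names(ccfs), strength = unname(strengths))
    ),
    class = "coupling_group"
  )
}

#' @export
print.coupling_group <- function(x, ...) {
  cat(sprintf(
    "<coupling_group> %d subjects; chosen lag %+.3g s; mean strength %.3f\n",
    nrow(x$subjects), x$chosen_lag, mean(x$subjects$strength, na.rm = TRUE)
  ))
  invisible(x)
}

#' Negative-derivative consistency check for BOLD-CSF coupling
#'
#' Computes the rectified negative derivative of the gBOLD signal
#' (`max(0, -dBOLD/dt)`) and its cross-correlation with the CSF series over
#' the same lag grid. A positive peak near zero lag indicates that CSF
#' inflow matches BOLD decreases, the expected physiological signature.
#'
#' @inheritParams bold_csf_ccf
#' @return A `coupling_ccf` tibble (positive peak expected); the rectified
#'   derivative is attached as attribute `"derivative"`. Note the "chosen
#'   lag" attributes still refer to the most negative correlation and are
#'   not meaningful for this check.
#' @export
neg_derivative_check <- function(gbold, csf, tr, max_lag = 10,
                                 min_overlap = 30) {
  check_scalar(tr, "tr", positive = TRUE)
  if (length(gbold) != length(csf)) abort("series must have equal length.")
  d <- pmax(0, -diff(gbold) / tr)
  out <- bold_csf_ccf(d, csf[-1], tr, max_lag, min_overlap)
  attr(out, "derivative") <- d
  out
}

#' Voxel-wise BOLD-CSF coupling averaged within networks
#'
#' For every voxel in the label volume, finds the negative peak of its
#' BOLD-CSF cross-correlation function (ties broken toward smaller |lag|,
#' then positive), takes the correlation there as the voxel's coupling
#' strength, and averages strengths within each network label.
#'
#' @param vbold 4-D [volume_grid()] (x, y, z, time).
#' @param csf CSF inflow series (length = number of volumes).
#' @param network_labels 3-D integer [volume_grid()]; positive values are
#'   network IDs.
#' @param tr Repetition time in seconds.
#' @param max_lag Maximum |lag| in seconds.
#' @param networks Optional vector of expected network IDs; IDs with no
#'   voxels yield an NA row with a warning.
#' @param min_overlap Minimum overlapping samples per correlation.
#' @return A tibble with columns `network`, `n_voxels`, `mean_strength`,
#'   `mean_lag`.
#' @export
network_coupling <- function(vbold, csf, network_labels, tr, max_lag = 10,
                             networks = NULL, min_overlap = 30) {
  if (!inherits(vbold, "volume_grid") || length(dim(vbold$data)) != 4) {
    abort("`vbold` must be a 4-D volume_grid.")
  }
  if (!identical(dim(vbold$data)[1:3], dim(network_labels$data)[1:3])) {
    abort("`network_labels` must share the vbold spatial grid.")
  }
  labs <- network_labels$data
  sel <- which(labs > 0)
  nt <- dim(vbold$data)[4]
  if (length(csf) != nt) abort("`csf` length must match the number of volumes.")
  mat <- matrix(vbold$data, ncol = nt)[sel, , drop = FALSE] # voxels x time
  ks <- lag_grid_samples(tr, max_lag)
  rmat <- matrix(NA_real_, length(sel), length(ks))
  n <- nt
  for (j in seq_along(ks)) {
    k <- ks[j]
    if (k >= 0) {
      ia <- seq_len(n - k)
      ib <- ia + k
    } else {
      ib <- seq_len(n + k)
      ia <- ib - k
    }
    if (length(ia) < min_overlap) next
    seg <- t(mat[, ia, drop = FALSE])
    sds <- apply(seg, 2, sd)
    r <- suppressWarnings(cor(seg, csf[ib]))
    r[sds == 0 | sd(csf[ib]) == 0] <- NA_real_
    rmat[, j] <- r
  }
  lags <- ks * tr
  vox_lag <- apply(rmat, 1, function(r) argmin_lag(lags, r))
  vox_strength <- rmat[cbind(seq_along(sel), match(vox_lag, lags))]
  ids <- labs[sel]
  networks <- networks %||% sort(unique(ids))
  rows <- lapply(networks, function(nw) {
    in_nw <- ids == nw
    if (!any(in_nw)) {
      warn(sprintf("network %s has no voxels; reported as NA.", format(nw)))
      return(tibble(
        network = nw, n_voxels = 0L,
        mean_strength = NA_real_, mean_lag = NA_real_
      ))
    }
    tibble(
      network = nw, n_voxels = sum(in_nw),
      mean_strength = mean(vox_strength[in_nw], na.rm = TRUE),
      mean_lag = mean(vox_lag[in_nw], na.rm = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}
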
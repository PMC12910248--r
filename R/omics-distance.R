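# Coerce to a samples-x-features numeric matrix; omics_table uses subjects.
values_matrix <- function(x) {
  if (inherits(x, "omics_table")) {
    sv <- subject_values(x)
    m <- sv$values
    rownames(m) <- sv$sample_id
    return(m)
  }
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, TRUE)
    m <- as.matrix(x[num])
    if ("sample_id" %in% names(x)) rownames(m) <- x$sample_id
    return(m)
  }
  as.matrix(x)
}

#' Bray-Curtis dissimilarity
#'
#' Compositional distance
#' \eqn{d(i, j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}
#' between nonnegative abundance profiles; symmetric, zero on the diagonal,
#' and bounded by 1.
#'
#' @param x Samples-x-features matrix, data frame, or [omics_table()]
#'   (subject samples used); entries must be nonnegative and no sample may
#'   be all zero.
#' @return A `dist` object.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(0.7, 0.3, 0), b = c(0.2, 0.3, 0.5)))
bray_curtis <- function(x) {
  m <- values_matrix(x)
  if (any(m < 0, na.rm = TRUE)) abort("Bray-Curtis needs nonnegative values.")
  zero <- rowSums(m) <= 0
  if (any(zero)) {
    bad <- rownames(m)[zero] %||% which(zero)
    abort(paste0("all-zero sample(s): ", paste(bad, collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Classical scaling of the Gower-centered squared-distance matrix.
#' Eigenvalues are reported in full, including negative ones (no
#' correction), as appropriate for non-Euclidean dissimilarities such as
#' Bray-Curtis. Coordinates are returned for the leading positive
#' eigenvalues only; each axis's sign is fixed by making its
#' largest-magnitude coordinate positive.
#'
#' @param d A `dist` object or square symmetric matrix with zero diagonal.
#' @param k Number of axes requested.
#' @return An object of class `pcoa_ord`: `points` (tibble with `sample_id`
#'   and `Axis.1..k`), `eig` (all eigenvalues), `var_explained` (relative to
#'   the positive-eigenvalue total).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1) abort("`k` must be >= 1.")
  cs <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cs$eig
  n_pos <- sum(eig > max(eig) * 1e-9)
  if (k > n_pos) {
    warn(sprintf(
      "only %d positive eigenvalues; returning %d axes instead of %d.",
      n_pos, n_pos, k
    ))
    k <- n_pos
  }
  pts <- cs$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("Axis.", seq_len(k))
  ids <- attr(d, "Labels") %||% paste0("S", seq_len(n))
  structure(
    list(
      points = dplyr::bind_cols(tibble(sample_id = ids), as_tibble(as.data.frame(pts))),
      eig = eig,
      var_explained = pmax(eig, 0)[seq_len(k)] / sum(pmax(eig, 0))
    ),
    class = "pcoa_ord"
  )
}

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- ncol(x$points) - 1
  cat(sprintf(
    "<pcoa_ord> %d samples, %d axes (%s of positive inertia)\n",
    nrow(x$points), k,
    paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " + ")
  ))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: the pseudo-F statistic from
#' the within/between partition of squared distances, with a permutation
#' p-value \eqn{p = (1 + \#\{F^{perm} \ge F\}) / (1 + n_{perm})} under
#' seeded label permutation. Backed by `vegan::adonis2`, seeded locally so a
#' fixed seed reproduces the p-value bit for bit.
#'
#' @param d A `dist` object or square symmetric distance matrix.
#' @param groups Group label per sample; >= 2 groups with >= 2 samples each.
#' @param n_perm Number of permutations (the convention for this analysis
#'   is 1000).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permanova_result` with `pseudo_F`, `p_value`,
#'   `n_perm`, `df`, `r_squared`. `tidy()` returns a one-row tibble.
#' @export
permanova <- function(d, groups, n_perm = 1000, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) {
    abort("`groups` length must match the distance matrix.")
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 samples each.")
  }
  fit <- with_local_seed(seed, {
    vegan::adonis2(d ~ g, data = data.frame(g = groups), permutations = n_perm)
  })
  structure(
    list(
      pseudo_F = fit$F[1],
      p_value = fit$`Pr(>F)`[1],
      n_perm = n_perm,
      df = c(fit$Df[1], fit$Df[nrow(fit) - 1]),
      r_squared = fit$R2[1],
      seed = seed
    ),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "<permanova> pseudo-F(%d, %d) = %.4f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$df[1], x$df[2], x$pseudo_F, x$r_squared, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @rdname permanova
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.permanova_result <- function(x, ...) {
  tibble(
    pseudo_F = x$pseudo_F, df1 = x$df[1], df2 = x$df[2],
    r_squared = x$r_squared, p_value = x$p_value, n_perm = x$n_perm
  )
}
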
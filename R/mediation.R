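#' Partial Spearman correlation
#'
#' Rank correlation between two variables after removing covariate effects:
#' both variables are mid-ranked, each rank vector is residualized on the
#' covariates (with intercept) by ordinary least squares, and the Pearson
#' correlation of the residuals is reported with a t-approximation p-value
#' on n - 2 - q degrees of freedom (q covariates). With no covariates this
#' is the classical Spearman correlation.
#'
#' @param data Data frame with one row per subject.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate column names, or `NULL`.
#' @return A one-row tibble: `rho`, `statistic`, `df`, `p_value`, `n`.
#'   `rho` is `NA` when either variable is constant.
#' @export
#' @examples
#' df <- data.frame(a = rnorm(30), b = rnorm(30), age = rnorm(30))
#' partial_spearman(df, "a", "b", "age")
partial_spearman <- function(data, x, y, covariates = NULL) {
  xv <- as.numeric(pull_col(data, x))
  yv <- as.numeric(pull_col(data, y))
  C <- covariate_matrix(data, covariates)
  keep <- is.finite(xv) & is.finite(yv)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  xv <- xv[keep]
  yv <- yv[keep]
  C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  n <- length(xv)
  q <- if (is.null(C)) 0 else ncol(C)
  if (n <= q + 2) abort("need n > number of covariates + 2.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble(
      rho = NA_real_, statistic = NA_real_, df = n - 2 - q,
      p_value = NA_real_, n = n
    ))
  }
  rx <- ols_residuals(rank(xv), C)
  ry <- ols_residuals(rank(yv), C)
  rho <- cor(rx, ry)
  df <- n - 2 - q
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble(
    rho = rho, statistic = tstat, df = df,
    p_value = 2 * pt(-abs(tstat), df), n = n
  )
}

# Fast OLS via QR, coefficients restored to input column order; NULL when
# the design is singular.
fast_ols <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    return(NULL)
  }
  b <- numeric(ncol(X))
  b[fit$pivot] <- fit$coefficients
  b
}

# As fast_ols but also returns classical standard errors.
ols_coef <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    return(NULL)
  }
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  qr_obj <- structure(
    list(qr = fit$qr, rank = fit$rank, qraux = fit$qraux, pivot = fit$pivot),
    class = "qr"
  )
  XtXinv <- chol2inv(qr.R(qr_obj))
  b <- numeric(p)
  se <- numeric(p)
  b[fit$pivot] <- fit$coefficients
  se[fit$pivot] <- sqrt(sigma2 * diag(XtXinv))
  list(coef = b, se = se)
}

# The four structural fits of the serial two-mediator model, given the full
# design blocks. Zxc columns: intercept, x, covariates. Returns the seven
# path coefficients or NULL on any singular fit.
serial_paths <- function(Zxc, m1, m2, y) {
  b1f <- fast_ols(Zxc, m1) # M1 ~ X + C
  if (is.null(b1f)) {
    return(NULL)
  }
  b2f <- fast_ols(cbind(Zxc, m1), m2) # M2 ~ X + M1 + C
  if (is.null(b2f)) {
    return(NULL)
  }
  b3f <- fast_ols(cbind(Zxc, m1, m2), y) # Y ~ X + M1 + M2 + C
  if (is.null(b3f)) {
    return(NULL)
  }
  b4f <- fast_ols(Zxc, y) # Y ~ X + C (total effect)
  if (is.null(b4f)) {
    return(NULL)
  }
  p <- ncol(Zxc)
  c(
    a1 = b1f[2],
    a2 = b2f[2],
    d = b2f[p + 1],
    c_prime = b3f[2],
    b1 = b3f[p + 1],
    b2 = b3f[p + 2],
    c = b4f[2]
  )
}

# Path coefficients from the Gram matrix G = crossprod([1, x, C, m1, m2, y])
# with pz = ncol([1, x, C]). NULL when any normal-equation solve fails.
serial_paths_gram <- function(G, pz) {
  sol <- function(pred, target) {
    tryCatch(
      solve(G[pred, pred, drop = FALSE], G[pred, target]),
      error = function(e) NULL
    )
  }
  i1 <- seq_len(pz)
  b1f <- sol(i1, pz + 1) # M1 ~ X + C
  b2f <- sol(c(i1, pz + 1), pz + 2) # M2 ~ X + M1 + C
  b3f <- sol(c(i1, pz + 1, pz + 2), pz + 3) # Y ~ X + M1 + M2 + C
  b4f <- sol(i1, pz + 3) # Y ~ X + C
  if (is.null(b1f) || is.null(b2f) || is.null(b3f) || is.null(b4f)) {
    return(NULL)
  }
  c(
    a1 = b1f[2], a2 = b2f[2], d = b2f[pz + 1],
    c_prime = b3f[2], b1 = b3f[pz + 1], b2 = b3f[pz + 2],
    c = b4f[2]
  )
}

#' Serial two-mediator mediation with bootstrap confidence intervals
#'
#' Fits the serial mediation model X -> M1 -> M2 -> Y by four ordinary
#' least-squares regressions (each with intercept and covariates):
#' M1 ~ X; M2 ~ X + M1; Y ~ X + M1 + M2; and Y ~ X (total effect). The
#' total effect decomposes exactly as
#' \deqn{c = c' + a_1 b_1 + a_2 b_2 + a_1 d b_2}
#' into the direct effect and the three indirect pathways through M1, M2,
#' and M1 then M2; the identity is verified at run time and reported as
#' `identity_gap`. Confidence intervals are percentile intervals from a
#' nonparametric case-resampling bootstrap (rows resampled with
#' replacement, all equations refit) with a fixed seed; an effect is
#' flagged significant when its interval excludes zero. Bootstrap draws
#' with a singular design are discarded and redrawn (counted; a warning is
#' issued above 1% discards). Analysis is complete-case.
#'
#' @param data Data frame with one row per subject.
#' @param x,m1,m2,y Column names of the exposure, first mediator (e.g. a
#'   plasma metabolite), second mediator (e.g. a glymphatic marker), and
#'   outcome.
#' @param covariates Character vector of covariate column names (binary
#'   covariates coded 0/1), or `NULL`.
#' @param n_boot Number of bootstrap resamples (convention: 5000).
#' @param seed Integer seed; fixed seed gives bit-identical intervals.
#' @param conf_level Confidence level for the percentile intervals.
#' @return An object of class `serial_mediation`; see [tidy()] /
#'   [glance()] methods.
#' @export
#' @examples
#' cohort <- gen_mediation_cohort(cohort_truth(c(20, 20, 20), seed = 7), n = 120)
#' fit <- serial_mediation(cohort, "x", "m1", "m2", "y",
#'   covariates = c("c1", "c2"), n_boot = 200, seed = 1
#' )
#' tidy(fit)
serial_mediation <- function(data, x, m1, m2, y, covariates = NULL,
                             n_boot = 5000, seed = 1L, conf_level = 0.95) {
  vars <- c(x, m1, m2, y)
  for (v in vars) pull_col(data, v)
  C <- covariate_matrix(data, covariates)
  df <- data.frame(
    x = as.numeric(data[[x]]), m1 = as.numeric(data[[m1]]),
    m2 = as.numeric(data[[m2]]), y = as.numeric(data[[y]])
  )
  keep <- stats::complete.cases(df)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  df <- df[keep, ]
  C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  n <- nrow(df)
  q <- if (is.null(C)) 0 else ncol(C)
  if (n <= q + 4) abort("need n > number of covariates + 4 complete cases.")
  check_full_rank(cbind(x = df$x, C))

  Zxc <- cbind(1, df$x, C)
  paths <- serial_paths(Zxc, df$m1, df$m2, df$y)
  if (is.null(paths)) abort("singular design in the point fit.")

  # standard errors per equation
  se_of <- function(X, yv, col) {
    fit <- ols_coef(X, yv)
    fit$se[col]
  }
  ses <- c(
    a1 = se_of(Zxc, df$m1, 2),
    a2 = se_of(cbind(Zxc, df$m1), df$m2, 2),
    d = se_of(cbind(Zxc, df$m1), df$m2, ncol(Zxc) + 1),
    c_prime = se_of(cbind(Zxc, df$m1, df$m2), df$y, 2),
    b1 = se_of(cbind(Zxc, df$m1, df$m2), df$y, ncol(Zxc) + 1),
    b2 = se_of(cbind(Zxc, df$m1, df$m2), df$y, ncol(Zxc) + 2),
    c = se_of(Zxc, df$y, 2)
  )

  effects_of <- function(p) {
    c(
      c = unname(p["c"]),
      c_prime = unname(p["c_prime"]),
      ie1 = unname(p["a1"] * p["b1"]),
      ie2 = unname(p["a2"] * p["b2"]),
      ie3 = unname(p["a1"] * p["d"] * p["b2"])
    )
  }
  est <- effects_of(paths)
  identity_gap <- abs(est["c"] - (est["c_prime"] + est["ie1"] + est["ie2"] + est["ie3"]))

  n_discard <- 0L
  boot <- NULL
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 5)
    colnames(boot) <- names(est)
    # bootstrap refits go through normal-equation solves on the Gram matrix
    # of the full design (one crossprod per draw), much faster than four QRs
    M <- cbind(Zxc, df$m1, df$m2, df$y)
    pz <- ncol(Zxc)
    with_local_seed(seed, {
      b <- 1L
      attempts <- 0L
      while (b <= n_boot && attempts < 10L * n_boot) {
        attempts <- attempts + 1L
        idx <- sample.int(n, n, replace = TRUE)
        p <- serial_paths_gram(crossprod(M[idx, , drop = FALSE]), pz)
        if (is.null(p)) {
          n_discard <- n_discard + 1L
          next
        }
        boot[b, ] <- effects_of(p)
        b <- b + 1L
      }
      if (b <= n_boot) abort("too many singular bootstrap draws; check the design.")
    })
    if (n_discard > 0.01 * n_boot) {
      warn(sprintf(
        "%d bootstrap draws (%.1f%%) discarded for singular designs.",
        n_discard, 100 * n_discard / n_boot
      ))
    }
  }

  alpha <- (1 - conf_level) / 2
  # Efron's order-statistic percentile convention (quantile type 6)
  ci <- if (is.null(boot)) {
    matrix(NA_real_, 2, 5, dimnames = list(NULL, names(est)))
  } else {
    apply(boot, 2, quantile,
      probs = c(alpha, 1 - alpha), names = FALSE, type = 6
    )
  }
  effects <- tibble(
    effect = names(est),
    pathway = c(
      "total", "direct",
      "x -> m1 -> y", "x -> m2 -> y", "x -> m1 -> m2 -> y"
    ),
    estimate = unname(est),
    conf_low = ci[1, ],
    conf_high = ci[2, ],
    significant = is.finite(ci[1, ]) & (ci[1, ] > 0 | ci[2, ] < 0)
  )
  structure(
    list(
      paths = tibble(
        term = names(paths), estimate = unname(paths),
        std_error = unname(ses[names(paths)])
      ),
      effects = effects,
      boot = boot,
      n = n, n_boot = n_boot, n_discard = n_discard,
      seed = as.integer(seed), conf_level = conf_level,
      identity_gap = unname(identity_gap),
      covariates = covariates %||% character()
    ),
    class = "serial_mediation"
  )
}

#' @export
print.serial_mediation <- function(x, ...) {
  cat(sprintf(
    "<serial_mediation> n = %d, %d covariates, %d bootstrap draws (seed %d)\n",
    x$n, length(x$covariates), x$n_boot, x$seed
  ))
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a serial mediation fit
#'
#' @param x A [serial_mediation()] result.
#' @param type `"effects"` (default: total/direct/indirect decomposition with
#'   bootstrap intervals) or `"paths"` (the seven regression coefficients
#'   with standard errors).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.serial_mediation <- function(x, type = c("effects", "paths"), ...) {
  type <- match.arg(type)
  if (type == "effects") x$effects else x$paths
}

#' @rdname tidy.serial_mediation
#' @exportS3Method generics::glance
glance.serial_mediation <- function(x, ...) {
  tibble(
    n = x$n, n_boot = x$n_boot, n_discard = x$n_discard,
    conf_level = x$conf_level, identity_gap = x$identity_gap,
    seed = x$seed
  )
}

#' Run serial mediation over a grid of candidate variable triples
#'
#' Batch driver over every combination of exposure, first mediator, second
#' mediator, and outcome column, each fitted by [serial_mediation()] with a
#' child seed derived deterministically from the master seed and the
#' combination key (so adding combinations never perturbs others). No
#' multiplicity correction is applied across models.
#'
#' @param data Data frame with one row per subject.
#' @param x_set,m1_set,m2_set,y_set Character vectors of candidate column
#'   names for each role.
#' @param covariates Covariate column names shared by all models.
#' @param n_boot,seed,conf_level Passed to [serial_mediation()].
#' @return A tibble keyed by (`x`, `m1`, `m2`, `y`) with one row per effect
#'   per combination, plus the child `seed` used.
#' @export
mediation_grid <- function(data, x_set, m1_set, m2_set, y_set,
                           covariates = NULL, n_boot = 5000, seed = 1L,
                           conf_level = 0.95) {
  combos <- tidyr::expand_grid(x = x_set, m1 = m1_set, m2 = m2_set, y = y_set)
  missing <- setdiff(
    unique(c(x_set, m1_set, m2_set, y_set, covariates)),
    names(data)
  )
  if (length(missing) > 0) {
    abort(paste0("variable(s) not in `data`: ", paste(missing, collapse = ", ")))
  }
  purrr::pmap_dfr(combos, function(x, m1, m2, y) {
    child <- derive_seed(seed, x, m1, m2, y)
    fit <- serial_mediation(data, x, m1, m2, y,
      covariates = covariates,
      n_boot = n_boot, seed = child, conf_level = conf_level
    )
    dplyr::bind_cols(
      tibble(x = x, m1 = m1, m2 = m2, y = y, seed = child),
      fit$effects
    )
  })
}
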
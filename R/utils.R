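# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a key
#'
#' Hierarchical seeding: every stage or grid cell derives its own stream from
#' the master seed plus a string key, so adding one analysis never perturbs
#' another's random numbers. The result is always a valid 31-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "permanova", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Column extraction with a helpful error.
pull_col <- function(data, name, what = "column") {
  if (!name %in% names(data)) {
    abort(sprintf("%s '%s' not found in `data`.", what, name))
  }
  data[[name]]
}

# Build a numeric covariate matrix (factors/characters dummy-coded, logicals
# and two-level variables coded 0/1). Returns NULL when no covariates.
covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(NULL)
  }
  missing <- setdiff(covariates, names(data))
  if (length(missing) > 0) {
    abort(paste0("covariate(s) not found: ", paste(missing, collapse = ", ")))
  }
  sub <- data[covariates]
  mm <- stats::model.matrix(~., data = as.data.frame(sub))
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# Error if columns of cbind(1, C) are collinear; names the offenders.
check_full_rank <- function(C) {
  if (is.null(C)) {
    return(invisible(NULL))
  }
  X <- cbind(`(Intercept)` = 1, C)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste0(
      "collinear covariates: ",
      paste(dropped, collapse = ", ")
    ))
  }
  invisible(NULL)
}

# OLS residuals of y on [1, C]; y itself when C is NULL.
ols_residuals <- function(y, C) {
  if (is.null(C)) {
    return(y - mean(y))
  }
  X <- cbind(1, C)
  stats::lm.fit(X, y)$residuals
}

# Check that a value is a single finite number.
check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
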
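# Internal helpers shared across modules.

#' Signal a classed screenflux error
#'
#' All user-facing validation failures raise conditions with a package-
#' specific class so callers (and tests) can distinguish failure modes.
#'
#' @param msg message text.
#' @param class condition subclass, e.g. "screenflux_invalid_spec".
#' @noRd
sf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "screenflux_error")))
}

#' Evaluate code under a fixed RNG seed, restoring global RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sf_stop("`seed` must be a single integer", "screenflux_invalid_parameter")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Check a scalar is a positive (or non-negative) number
#' @noRd
assert_scalar_number <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x)
  if (ok && positive) ok <- if (allow_zero) x >= 0 else x > 0
  if (!ok) {
    sf_stop(sprintf("`%s` must be a single %s number", name,
                    if (!positive) "finite" else if (allow_zero) "non-negative" else "positive"),
            "screenflux_invalid_parameter")
  }
  invisible(x)
}

#' Ordinary least squares slope with standard error
#'
#' Thin wrapper around `stats::lm.fit` returning slope, intercept, the
#' slope's standard error and R-squared. Used by the rate estimators and
#' standard-curve fits.
#'
#' @param x,y numeric vectors of equal length (>= 2 distinct x).
#' @return list(slope, intercept, se, r_squared, n).
#' @noRd
ols_line <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    sf_stop("need >= 2 paired points for a regression line",
            "screenflux_insufficient_points")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- length(x) - 2L
  if (df > 0) {
    s2 <- sum(res^2) / df
    xc <- x - mean(x)
    se <- sqrt(s2 / sum(xc^2))
  } else {
    se <- NA_real_
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
       se = se, r_squared = r2, n = length(x))
}
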
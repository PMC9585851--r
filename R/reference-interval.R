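new_reference_interval <- function(lower, upper, level, method,
                                   transform = NULL, n_used,
                                   clipped = FALSE) {
  structure(
    list(lower = lower, upper = upper, level = level, method = method,
         transform = transform, n_used = n_used, clipped = clipped),
    class = "reference_interval"
  )
}

#' Transformed parametric reference interval
#'
#' Box-Cox transforms the values toward normality, takes
#' `mean +/- z * sd` on the transformed scale at the exact standard
#' normal quantile z for the coverage level, and back-transforms the two
#' limits. If the inverse is undefined at a limit (the Gaussian limit
#' falls outside the transform's range) the limit is clipped to the
#' domain boundary and the result flagged, not an error.
#'
#' @param values numeric vector, at least 20 non-constant values.
#' @param level coverage probability of the interval (default 0.95).
#' @return an object of class `reference_interval` with the fitted
#'   `boxcox_transform` attached.
#' @examples
#' parametric_ri(rlnorm(500))
#' @export
parametric_ri <- function(values, level = 0.95) {
  x <- as.numeric(values)
  if (length(x) < 20L)
    stop("parametric_ri needs at least 20 values", call. = FALSE)
  stopifnot(level > 0, level < 1, all(is.finite(x)))
  if (max(x) == min(x))
    stop("parametric_ri undefined for constant data", call. = FALSE)
  tr <- boxcox_fit(x)
  y <- boxcox_apply(x, tr)
  m <- mean(y)
  s <- stats::sd(y)
  z <- stats::qnorm((1 + level) / 2)
  lims_t <- c(m - z * s, m + z * s)
  lam <- tr$lambda
  clipped <- FALSE
  invert_one <- function(yy, side) {
    if (lam != 0 && lam * yy + 1 <= 0) {
      clipped <<- TRUE
      # domain boundary of the inverse: x -> -shift as lam*y+1 -> 0+ for
      # lam > 0; x -> +Inf for lam < 0
      if (lam > 0) return(-tr$shift)
      return(Inf)
    }
    boxcox_invert(yy, tr)
  }
  lower <- invert_one(lims_t[1], "lower")
  upper <- invert_one(lims_t[2], "upper")
  new_reference_interval(lower, upper, level,
                         method = "transformed_parametric",
                         transform = tr, n_used = length(x),
                         clipped = clipped)
}

#' Non-parametric reference interval
#'
#' The empirical central interval: the (1-level)/2 and (1+level)/2
#' sample percentiles under the package-wide quantile convention
#' ([ri_quantile()]); 2.5th and 97.5th percentiles at the default level.
#'
#' @inheritParams parametric_ri
#' @return an object of class `reference_interval` (no transform).
#' @examples
#' nonparametric_ri(rnorm(500, 10))
#' @export
nonparametric_ri <- function(values, level = 0.95) {
  x <- as.numeric(values)
  if (length(x) < 20L)
    stop("nonparametric_ri needs at least 20 values", call. = FALSE)
  stopifnot(level > 0, level < 1, all(is.finite(x)))
  q <- ri_quantile(x, c((1 - level) / 2, (1 + level) / 2))
  new_reference_interval(q[1], q[2], level, method = "nonparametric",
                         transform = NULL, n_used = length(x))
}

#' @export
print.reference_interval <- function(x, digits = 4, ...) {
  lab <- switch(x$method,
                transformed_parametric = "transformed parametric",
                nonparametric = "non-parametric",
                x$method)
  cat(sprintf("%g%% reference interval (%s, n = %d): [%s, %s]%s\n",
              100 * x$level, lab, x$n_used,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              if (isTRUE(x$clipped)) "  [limit clipped at domain boundary]"
              else ""))
  if (!is.null(x$transform))
    cat(sprintf("  Box-Cox lambda = %.3f, shift = %g\n",
                x$transform$lambda, x$transform$shift))
  invisible(x)
}
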
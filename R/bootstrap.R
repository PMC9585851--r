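# Lean per-resample limit computation (no S3 allocation inside the
# bootstrap loop). Returns c(lower, upper) or NULL for a degenerate
# (constant) resample under the parametric method.
.limits_one <- function(x, method, level) {
  if (method == "nonparametric") {
    return(ri_quantile(x, c((1 - level) / 2, (1 + level) / 2)))
  }
  if (max(x) == min(x)) return(NULL)
  tr <- boxcox_fit(x)
  y <- boxcox_apply(x, tr)
  m <- mean(y)
  s <- stats::sd(y)
  z <- stats::qnorm((1 + level) / 2)
  lam <- tr$lambda
  out <- numeric(2)
  yy <- c(m - z * s, m + z * s)
  for (i in 1:2) {
    if (lam != 0 && lam * yy[i] + 1 <= 0) {
      out[i] <- if (lam > 0) -tr$shift else Inf
    } else {
      out[i] <- boxcox_invert(yy[i], tr)
    }
  }
  out
}

#' Bootstrap the reference-limit distribution at one candidate n
#'
#' The inner layer of the estimator: draws `B` resamples of size `n`
#' with replacement from the population and computes the reference
#' interval on each by the requested method, yielding the bootstrap
#' distributions of the lower and upper limits and of the RI width.
#' Degenerate resamples (constant values, for which the Box-Cox
#' likelihood is undefined) are redrawn, up to `10 * B` attempts in
#' total, so that all `B` replicates are effective; the number of
#' redraws is recorded.
#'
#' @param pop an `analyte_population` (or numeric vector).
#' @param n resample size, at least 20.
#' @param B number of bootstrap replicates, at least 2.
#' @param method `"parametric"` (Box-Cox transformed parametric) or
#'   `"nonparametric"`.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param ri_level coverage of the reference interval (default 0.95).
#' @return an object of class `limit_distribution`: list with `n`,
#'   `method`, `lowers`, `uppers`, `widths` (each length B), `B` and
#'   `redraws`.
#' @examples
#' pop <- ri_population(rnorm(2000, 10))
#' d <- resample_limits(pop, n = 100, B = 50, method = "nonparametric",
#'                      seed = 1)
#' percentile_ci(d$uppers)
#' @export
resample_limits <- function(pop, n, B, method = c("parametric",
                                                  "nonparametric"),
                            seed = 1L, ri_level = 0.95) {
  pop <- as_ri_population(pop)
  method <- match.arg(method)
  stopifnot(n >= 20L, B >= 2L)
  vals <- pop$values
  if (method == "parametric" && max(vals) == min(vals))
    stop("population is degenerate (constant): parametric limits at n = ",
         n, " cannot be bootstrapped", call. = FALSE)
  set.seed(as.integer(seed))
  lowers <- numeric(B)
  uppers <- numeric(B)
  redraws <- 0L
  budget <- 10L * B
  draws <- 0L
  i <- 1L
  while (i <= B) {
    if (draws >= budget + B)
      stop("redraw budget exhausted bootstrapping ", method,
           " limits at n = ", n, call. = FALSE)
    x <- vals[sample.int(length(vals), n, replace = TRUE)]
    draws <- draws + 1L
    lim <- .limits_one(x, method, ri_level)
    if (is.null(lim)) {
      redraws <- redraws + 1L
      next
    }
    lowers[i] <- lim[1]
    uppers[i] <- lim[2]
    i <- i + 1L
  }
  structure(
    list(n = as.integer(n), method = method, lowers = lowers,
         uppers = uppers, widths = uppers - lowers, B = as.integer(B),
         redraws = redraws),
    class = "limit_distribution"
  )
}

#' @export
print.limit_distribution <- function(x, ...) {
  cat(sprintf(
    "Bootstrap limit distribution: %s, n = %d, B = %d (%d redraws)\n",
    x$method, x$n, x$B, x$redraws))
  cat(sprintf("  lower limit: mean %.4g, 90%% CI [%.4g, %.4g]\n",
              mean(x$lowers), percentile_ci(x$lowers)[1],
              percentile_ci(x$lowers)[2]))
  cat(sprintf("  upper limit: mean %.4g, 90%% CI [%.4g, %.4g]\n",
              mean(x$uppers), percentile_ci(x$uppers)[1],
              percentile_ci(x$uppers)[2]))
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' The percentile-method CI of a bootstrap statistic: the
#' (1-level)/2 and (1+level)/2 percentiles of the replicates under the
#' package quantile convention (5th and 95th at the default 90% level).
#'
#' @param samples numeric vector of bootstrap replicates (at least 2).
#' @param level confidence level (default 0.90).
#' @return length-2 numeric vector `c(lo, hi)`.
#' @export
percentile_ci <- function(samples, level = 0.90) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 2L, level > 0, level < 1)
  ri_quantile(samples, c((1 - level) / 2, (1 + level) / 2))
}

#' Scalar summary of the bootstrap RI widths
#'
#' Reduces the B bootstrap RI widths to the scalar used as the
#' denominator of the convergence ratios. The default is the median;
#' the four quintile cut points and the mean are available for
#' sensitivity analysis.
#'
#' @param dist a `limit_distribution` from [resample_limits()].
#' @param summary one of `"median"`, `"mean"`, `"quintile1"` ..
#'   `"quintile4"` (the 20/40/60/80th percentiles).
#' @return a single number in analyte units.
#' @export
width_summary <- function(dist, summary = "median") {
  stopifnot(inherits(dist, "limit_distribution"), length(dist$widths) >= 1L)
  w <- dist$widths
  switch(summary,
    median = ri_quantile(w, 0.5),
    mean = mean(w),
    quintile1 = ri_quantile(w, 0.2),
    quintile2 = ri_quantile(w, 0.4),
    quintile3 = ri_quantile(w, 0.6),
    quintile4 = ri_quantile(w, 0.8),
    stop("unknown width summary '", summary, "'; use median, mean or ",
         "quintile1..quintile4", call. = FALSE)
  )
}
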
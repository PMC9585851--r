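#' Reference population container
#'
#' Wraps one analyte's measurements for a reference population. The
#' object is the unit the bootstrap samples from; it is never mutated by
#' the search (outlier filtering happens once, up front, producing a new
#' population).
#'
#' @param values numeric vector of finite measurements, in analyte units.
#' @param analyte label for the analyte (e.g. `"TSH"`).
#' @param unit measurement unit label (e.g. `"uIU/mL"`).
#' @return an object of class `analyte_population`: a list with elements
#'   `values`, `analyte`, `unit` and `n`.
#' @examples
#' pop <- ri_population(rnorm(500, 10), analyte = "demo", unit = "au")
#' pop
#' @export
ri_population <- function(values, analyte = "analyte", unit = "") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("a population needs at least one value", call. = FALSE)
  if (!all(is.finite(values)))
    stop("population values must all be finite; drop NA/Inf before ",
         "constructing the population", call. = FALSE)
  structure(
    list(values = values, analyte = as.character(analyte)[1L],
         unit = as.character(unit)[1L], n = length(values)),
    class = "analyte_population"
  )
}

as_ri_population <- function(x, analyte = "analyte", unit = "") {
  if (inherits(x, "analyte_population")) return(x)
  if (is.numeric(x)) return(ri_population(x, analyte, unit))
  stop("cannot interpret 'x' as a reference population; supply a numeric ",
       "vector or an analyte_population", call. = FALSE)
}

#' @export
print.analyte_population <- function(x, ...) {
  cat(sprintf("Reference population: %s (n = %d%s)\n", x$analyte, x$n,
              if (nzchar(x$unit)) paste0(", ", x$unit) else ""))
  q <- ri_quantile(x$values, c(0.025, 0.25, 0.5, 0.75, 0.975))
  cat(sprintf("  median %.4g (2.5%%: %.4g, 97.5%%: %.4g)\n",
              q[3], q[1], q[5]))
  invisible(x)
}

#' Tukey fence outlier identification
#'
#' Flags values outside the Tukey fences Q1 - 1.5 IQR and Q3 + 1.5 IQR,
#' with quartiles computed under the package-wide quantile convention
#' (see [ri_quantile()]). Applied once to the raw population before any
#' sample-size search; values are kept in input order.
#'
#' @param values numeric vector with at least 4 values (quartiles must be
#'   defined).
#' @return an object of class `tukey_filter`: list with `kept`, `removed`,
#'   `lower_fence`, `upper_fence`.
#' @examples
#' tukey_filter(c(1:10, 1000))
#' @export
tukey_filter <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("tukey_filter needs at least 4 values (quartiles undefined below ",
         "that)", call. = FALSE)
  if (!all(is.finite(values)))
    stop("tukey_filter requires finite values", call. = FALSE)
  q <- ri_quantile(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  structure(
    list(kept = values[inside], removed = values[!inside],
         lower_fence = lo, upper_fence = hi),
    class = "tukey_filter"
  )
}

#' @export
print.tukey_filter <- function(x, ...) {
  cat(sprintf("Tukey outlier filter: fences [%.4g, %.4g]; kept %d, removed %d\n",
              x$lower_fence, x$upper_fence, length(x$kept), length(x$removed)))
  invisible(x)
}

#' Normality assessment with the Lilliefors-corrected KS test
#'
#' Tests the composite hypothesis that the data are normal with unknown
#' mean and variance, using the Kolmogorov-Smirnov statistic against a
#' normal distribution with parameters estimated from the data and the
#' Lilliefors p-value correction (a plain KS test against fixed
#' parameters would be anti-conservative). The report is descriptive:
#' the transformed parametric estimator always applies Box-Cox, whatever
#' this test says.
#'
#' @param values numeric vector, at least 5 values.
#' @param alpha significance level used for the `is_normal` verdict.
#' @return an object of class `normality_report`: list with `statistic`
#'   (the KS sup-distance), `p_value`, `alpha`, `is_normal` and `note`.
#'   Constant input yields `is_normal = FALSE` with a degenerate-input
#'   note rather than an error.
#' @examples
#' ks_normality(rnorm(200))
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 5L)
    stop("ks_normality needs at least 5 values", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  if (stats::sd(values) == 0) {
    return(structure(
      list(statistic = NA_real_, p_value = NA_real_, alpha = alpha,
           is_normal = FALSE,
           note = "degenerate input: zero variance, normality undefined"),
      class = "normality_report"
    ))
  }
  ht <- nortest::lillie.test(values)
  p <- unname(ht$p.value)
  structure(
    list(statistic = unname(ht$statistic), p_value = p, alpha = alpha,
         is_normal = p >= alpha, note = NULL),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("Normality: ", x$note, "\n", sep = "")
  } else {
    cat(sprintf(
      "Lilliefors (KS) normality: D = %.4f, p = %.4g -> %s at alpha = %g\n",
      x$statistic, x$p_value,
      if (x$is_normal) "consistent with normal" else "not normal", x$alpha))
  }
  invisible(x)
}
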
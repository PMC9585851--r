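#' Control parameters for the sample-size search
#'
#' Collects the tuning constants of the estimator, with defaults set to
#' the published procedure: candidate sizes 40 to 2000 in steps of 1,
#' B = 1000 bootstrap resamples per size, a 95% reference interval, 90%
#' bootstrap confidence intervals of its limits, pass threshold 0.2 on
#' both CI-width/RI-width ratios, and smoothing window 10.
#'
#' @param n_min,n_max,step candidate-size grid bounds and step
#'   (`n_min >= 20`, `step >= 1`). Grids with `step > 1` report the grid
#'   value; resolution is then +/- step.
#' @param B bootstrap resamples per candidate size.
#' @param ri_level coverage of the reference interval (0.95).
#' @param ci_level level of the bootstrap CI of each limit (0.90).
#' @param threshold pass criterion: both ratios must be below this
#'   (0.2, the rule that a limit's CI should be narrower than 0.2 times
#'   the RI width).
#' @param window moving-sum / moving-median window width (10).
#' @param width_summary scalar summary of the B RI widths used as the
#'   ratio denominator; see [width_summary()].
#' @param seed root seed; every bootstrap draw in the search derives a
#'   deterministic child seed from it, so results do not depend on
#'   evaluation order or early stopping.
#' @param early_stop stop the sweep as soon as the stabilized estimate
#'   is final (it cannot change with further candidates); set `FALSE`
#'   to evaluate the full grid, e.g. for trace plots.
#' @param report_position mapping from the smoothed index back to a
#'   grid value; see [first_stable_n()].
#' @param tukey apply Tukey fence outlier filtering to the population
#'   once before the search (default TRUE).
#' @return a list of class `ri_control`.
#' @export
ri_control <- function(n_min = 40L, n_max = 2000L, step = 1L, B = 1000L,
                       ri_level = 0.95, ci_level = 0.90, threshold = 0.2,
                       window = 10L, width_summary = "median", seed = 1L,
                       early_stop = TRUE,
                       report_position = c("run_start", "window_end"),
                       tukey = TRUE) {
  report_position <- match.arg(report_position)
  stopifnot(n_min >= 20L, n_max >= n_min, step >= 1L, window >= 1L,
            threshold > 0, threshold < 1, B >= 2L,
            ri_level > 0, ri_level < 1, ci_level > 0, ci_level < 1)
  structure(
    list(n_min = as.integer(n_min), n_max = as.integer(n_max),
         step = as.integer(step), B = as.integer(B),
         ri_level = ri_level, ci_level = ci_level, threshold = threshold,
         window = as.integer(window), width_summary = width_summary,
         seed = as.integer(seed), early_stop = isTRUE(early_stop),
         report_position = report_position, tukey = isTRUE(tukey)),
    class = "ri_control"
  )
}

# Sweep one method over the candidate grid; returns the per-method fit.
run_search <- function(pop, method, control) {
  n_grid <- seq.int(control$n_min, control$n_max, by = control$step)
  w <- control$window
  rows <- vector("list", length(n_grid))
  flags <- integer(0)
  estimated_n <- NA_integer_
  k <- 0L
  for (n in n_grid) {
    k <- k + 1L
    rows[[k]] <- evaluate_n(pop, n, control, method)
    flags <- c(flags, rows[[k]]$flag)
    if (control$early_stop && length(flags) >= 2L * w - 1L) {
      est <- first_stable_n(flags, n_grid[seq_len(k)], w,
                            control$report_position)
      if (!is.na(est)) {
        estimated_n <- est
        break
      }
    }
  }
  trace <- do.call(rbind, rows[seq_len(k)])
  if (!control$early_stop || is.na(estimated_n)) {
    estimated_n <- first_stable_n(trace$flag, trace$n, w,
                                  control$report_position)
  }
  sums <- if (nrow(trace) >= w) moving_sum(trace$flag, w) else numeric(0)
  meds <- if (length(sums) >= w) moving_median(sums, w) else numeric(0)
  validation <- if (is.na(estimated_n)) c(R1 = NA_real_, R2 = NA_real_)
                else validate_at_n(pop, estimated_n, control, method)
  list(method = method, estimated_n = estimated_n, trace = trace,
       moving_sums = sums, moving_medians = meds,
       validation = validation, converged = !is.na(estimated_n))
}

#' Estimate the minimum sample size for establishing a reference interval
#'
#' The main fitting function. For each requested reference-interval
#' method it sweeps candidate sample sizes n over a grid, bootstraps the
#' 90% confidence intervals of the lower and upper reference limits at
#' each n (B resamples with replacement), forms the ratios
#' R1 = LLW_CI / W_RI and R2 = ULW_CI / W_RI of CI widths to the RI
#' width, flags sizes where both ratios fall below the threshold, and
#' stabilizes the flag sequence with a moving sum followed by a moving
#' median (window 10) to return the first *stably* converged size. The
#' ratios at the estimate are then re-measured with an independent seed
#' (the validation columns).
#'
#' Non-convergence by `n_max` is a first-class result (`estimated_n`
#' is NA and `converged` FALSE), not an error. The whole search is
#' deterministic given `control$seed`.
#'
#' @param x the reference population: a numeric vector or an
#'   `analyte_population` from [ri_population()].
#' @param method `"both"` (default), `"parametric"` (Box-Cox
#'   transformed parametric) or `"nonparametric"`.
#' @param control an [ri_control()] list of tuning constants.
#' @param analyte,unit labels used when `x` is a bare numeric vector.
#' @return an object of class `ri_samplesize`: list with elements
#'   `population` (the filtered population), `outliers` (the
#'   `tukey_filter` result, or NULL), `fits` (per-method list with
#'   `estimated_n`, `trace`, `moving_sums`, `moving_medians`,
#'   `validation`, `converged`), `control` and `call`. Methods:
#'   `print`, `summary`, `coef` (estimated sizes), `plot`.
#' @examples
#' pop <- generate_population(analyte_preset("ft4_like", pop_size = 2000,
#'                                           seed = 1))
#' fit <- ri_samplesize(pop, method = "parametric",
#'                      control = ri_control(B = 100, step = 20, seed = 1))
#' fit
#' @export
ri_samplesize <- function(x, method = c("both", "parametric",
                                        "nonparametric"),
                          control = ri_control(), analyte = "analyte",
                          unit = "") {
  method <- match.arg(method)
  stopifnot(inherits(control, "ri_control"))
  pop <- as_ri_population(x, analyte, unit)
  outliers <- NULL
  if (control$tukey) {
    outliers <- tukey_filter(pop$values)
    pop <- ri_population(outliers$kept, pop$analyte, pop$unit)
  }
  if (max(pop$values) == min(pop$values))
    stop("population is degenerate (constant) after filtering; the ",
         "sample-size search is undefined", call. = FALSE)
  methods <- if (method == "both") c("parametric", "nonparametric")
             else method
  fits <- lapply(methods, function(m) run_search(pop, m, control))
  names(fits) <- methods
  structure(
    list(population = pop, outliers = outliers, fits = fits,
         control = control, call = match.call()),
    class = "ri_samplesize"
  )
}

#' @export
print.ri_samplesize <- function(x, ...) {
  cat("Minimum sample size for reference interval establishment\n")
  cat(sprintf("  analyte: %s (n = %d%s)", x$population$analyte,
              x$population$n,
              if (nzchar(x$population$unit))
                paste0(", ", x$population$unit) else ""))
  if (!is.null(x$outliers))
    cat(sprintf("; Tukey-removed: %d", length(x$outliers$removed)))
  cat("\n")
  cat(sprintf("  grid %d..%d step %d, B = %d, threshold %.2g, window %d, seed %d\n",
              x$control$n_min, x$control$n_max, x$control$step,
              x$control$B, x$control$threshold, x$control$window,
              x$control$seed))
  for (f in x$fits) {
    lab <- if (f$method == "parametric") "transformed parametric"
           else "non-parametric"
    if (f$converged) {
      cat(sprintf("  %-23s n = %d  (validation LLW_CI/W_RI = %.3f, ULW_CI/W_RI = %.3f)\n",
                  lab, f$estimated_n, f$validation["R1"],
                  f$validation["R2"]))
    } else {
      cat(sprintf("  %-23s not converged by n_max = %d\n", lab,
                  x$control$n_max))
    }
  }
  invisible(x)
}

#' @export
summary.ri_samplesize <- function(object, ...) {
  out <- list(fit = object,
              table = do.call(rbind, lapply(object$fits, function(f) {
                data.frame(
                  method = f$method,
                  estimated_n = f$estimated_n,
                  converged = f$converged,
                  R1_validation = unname(f$validation["R1"]),
                  R2_validation = unname(f$validation["R2"]),
                  n_evaluated = nrow(f$trace),
                  row.names = NULL
                )
              })))
  class(out) <- "summary.ri_samplesize"
  out
}

#' @export
print.summary.ri_samplesize <- function(x, ...) {
  print(x$fit)
  cat("\nPer-method search summary:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ri_samplesize <- function(object, ...) {
  vapply(object$fits, function(f) as.numeric(f$estimated_n), numeric(1))
}

#' Trace plot of the convergence ratios against candidate sample size
#'
#' Plots R1 and R2 (limit-CI width over RI width) against the candidate
#' sample size for each fitted method, with the pass threshold and the
#' estimated minimum size marked. Mirrors the narrowing of the limit
#' confidence bands with increasing n.
#'
#' @param x an `ri_samplesize` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ri_samplesize <- function(x, ...) {
  nm <- length(x$fits)
  old <- graphics::par(mfrow = c(1, nm))
  on.exit(graphics::par(old))
  for (f in x$fits) {
    tr <- f$trace
    ylim <- range(c(tr$R1, tr$R2, x$control$threshold), na.rm = TRUE)
    graphics::plot(tr$n, tr$R1, type = "l", col = "steelblue",
                   xlab = "candidate sample size n",
                   ylab = expression(W[CI] / W[RI]),
                   ylim = ylim,
                   main = if (f$method == "parametric")
                     "transformed parametric" else "non-parametric", ...)
    graphics::lines(tr$n, tr$R2, col = "firebrick")
    graphics::abline(h = x$control$threshold, lty = 2)
    if (f$converged) graphics::abline(v = f$estimated_n, lty = 3)
    graphics::legend("topright", legend = c("R1 (lower limit)",
                                            "R2 (upper limit)"),
                     col = c("steelblue", "firebrick"), lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
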
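#' Moving (rolling) window sum
#'
#' Trailing contiguous windows: element i of the result is the sum of
#' `x[i .. i+w-1]`, so the output has length `length(x) - w + 1`.
#'
#' @param x numeric vector with `length(x) >= w`.
#' @param w window width, at least 1.
#' @return numeric vector of window sums.
#' @examples
#' moving_sum(c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 10)
#' @export
moving_sum <- function(x, w) {
  x <- as.numeric(x)
  w <- as.integer(w)
  stopifnot(w >= 1L)
  if (length(x) < w)
    stop("moving_sum needs at least w = ", w, " values, got ", length(x),
         call. = FALSE)
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

#' Moving (rolling) window median
#'
#' Trailing contiguous windows: element i of the result is the median of
#' `x[i .. i+w-1]`; the median of an even-length window is the mean of
#' the two central order statistics.
#'
#' @inheritParams moving_sum
#' @return numeric vector of window medians, length `length(x) - w + 1`.
#' @examples
#' moving_median(c(1, 2, 3, 4, 5), 3)
#' @export
moving_median <- function(x, w) {
  x <- as.numeric(x)
  w <- as.integer(w)
  stopifnot(w >= 1L)
  if (length(x) < w)
    stop("moving_median needs at least w = ", w, " values, got ",
         length(x), call. = FALSE)
  k <- length(x) - w + 1L
  vapply(seq_len(k),
         function(i) stats::median(x[i:(i + w - 1L)]),
         numeric(1))
}

#' First stably converged sample size
#'
#' The stabilization stage of the search: the 0/1 pass flags are
#' smoothed by a moving sum of width w, that sequence by a moving median
#' of width w, and the estimate is the candidate size where the moving
#' median first equals w (every flag in the neighbourhood passes). Two
#' index-to-n mappings are offered, since each smoothing pass shortens
#' the sequence by w - 1: `"run_start"` (default) reports the grid value
#' at the start of the earliest window contributing to the first
#' all-pass median — the beginning of the stable run; `"window_end"`
#' reports the grid value at the end of that double window,
#' `n_grid[j + 2(w-1)]`.
#'
#' @param flags integer 0/1 vector, one flag per candidate size.
#' @param n_grid candidate sizes, same length as `flags`.
#' @param window smoothing window width w (default 10).
#' @param report_position `"run_start"` or `"window_end"`.
#' @return the estimated minimum sample size, or `NA` if the moving
#'   median never reaches w (no convergence).
#' @examples
#' first_stable_n(rep(1, 30), 40:69)  # immediately stable -> 40
#' @export
first_stable_n <- function(flags, n_grid, window = 10L,
                           report_position = c("run_start", "window_end")) {
  report_position <- match.arg(report_position)
  w <- as.integer(window)
  stopifnot(length(flags) == length(n_grid), w >= 1L)
  if (length(flags) < 2L * w - 1L) return(NA_integer_)
  s <- moving_sum(flags, w)
  m <- moving_median(s, w)
  j <- which(m == w)
  if (length(j) == 0L) return(NA_integer_)
  j <- j[1L]
  idx <- if (report_position == "run_start") j
         else min(j + 2L * (w - 1L), length(n_grid))
  as.integer(n_grid[idx])
}

#' Evaluate one candidate sample size
#'
#' One step of the outer loop: bootstraps both reference limits at
#' size n ([resample_limits()]), takes the 90% percentile CI of each
#' limit ([percentile_ci()]), divides each CI width by the scalar
#' summary of the bootstrap RI widths ([width_summary()]) to get the
#' ratios R1 (lower limit) and R2 (upper limit), and flags the size as
#' passing when both ratios are below the threshold. A degenerate
#' denominator (zero RI width) yields flag 0 with a degenerate marker,
#' never a pass.
#'
#' @param pop an `analyte_population` (or numeric vector).
#' @param n candidate sample size.
#' @param control an [ri_control()] list.
#' @param method `"parametric"` or `"nonparametric"`.
#' @param seed optional integer seed overriding the control-derived
#'   child seed (used by the independent validation re-run).
#' @return one-row data frame with columns `n`, `ci_lower_width`,
#'   `ci_upper_width`, `ri_width_summary`, `R1`, `R2`, `flag`,
#'   `degenerate`, `redraws`.
#' @export
evaluate_n <- function(pop, n, control = ri_control(),
                       method = c("parametric", "nonparametric"),
                       seed = NULL) {
  pop <- as_ri_population(pop)
  method <- match.arg(method)
  if (is.null(seed))
    seed <- child_seed(control$seed, n, method, "search")
  dist <- resample_limits(pop, n = n, B = control$B, method = method,
                          seed = seed, ri_level = control$ri_level)
  ci_l <- percentile_ci(dist$lowers, control$ci_level)
  ci_u <- percentile_ci(dist$uppers, control$ci_level)
  wl <- ci_l[2] - ci_l[1]
  wu <- ci_u[2] - ci_u[1]
  wri <- width_summary(dist, control$width_summary)
  degenerate <- !is.finite(wri) || wri <= 0 || !is.finite(wl) ||
    !is.finite(wu)
  if (degenerate) {
    r1 <- NA_real_
    r2 <- NA_real_
    flag <- 0L
  } else {
    r1 <- wl / wri
    r2 <- wu / wri
    flag <- as.integer(r1 < control$threshold & r2 < control$threshold)
  }
  data.frame(n = as.integer(n), ci_lower_width = wl, ci_upper_width = wu,
             ri_width_summary = wri, R1 = r1, R2 = r2, flag = flag,
             degenerate = degenerate, redraws = dist$redraws)
}

#' Independent validation of the convergence ratios at a sample size
#'
#' Re-runs one bootstrap evaluation at `n` with a seed distinct from
#' the search seed and returns the two ratios (lower-limit CI width /
#' RI width, upper-limit CI width / RI width). Because this is a fresh
#' stochastic re-run, ratios at the estimated size are usually, but not
#' always, below the threshold.
#'
#' @inheritParams evaluate_n
#' @param seed integer seed for the re-run; defaults to a validation
#'   child seed distinct from every search child seed.
#' @return named numeric vector `c(R1 = ..., R2 = ...)` (NA if the
#'   evaluation is degenerate).
#' @export
validate_at_n <- function(pop, n, control = ri_control(),
                          method = c("parametric", "nonparametric"),
                          seed = NULL) {
  method <- match.arg(method)
  if (is.null(seed))
    seed <- child_seed(control$seed, n, method, "validation")
  row <- evaluate_n(pop, n, control, method, seed = seed)
  c(R1 = row$R1, R2 = row$R2)
}
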
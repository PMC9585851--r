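#' Package-wide quantile convention
#'
#' All percentile computations in the package (reference limits, bootstrap
#' confidence intervals, Tukey quartiles, RI-width summaries) use linear
#' interpolation of order statistics at plotting position k/(n+1)
#' (Weibull), i.e. the rank r = p(n+1) convention used by CLSI EP28-A3c
#' for non-parametric reference limits. Ranks outside \[1, n\] clip to the
#' extreme order statistics. This is `stats::quantile()` type 6.
#'
#' @param x numeric vector of finite values.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, unnamed.
#' @examples
#' ri_quantile(1:40, c(0.025, 0.975))
#' @export
ri_quantile <- function(x, probs) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  stopifnot(is.numeric(probs), all(probs >= 0), all(probs <= 1))
  unname(stats::quantile(x, probs = probs, type = 6, names = FALSE))
}

# Deterministic per-(n, method, role) child seed derived from the root
# seed. Keeps every draw reproducible and invariant to evaluation order
# and early stopping. Result is a valid 32-bit seed.
child_seed <- function(root_seed, n, method, role = "search") {
  method_code <- switch(method,
    parametric = 1L, nonparametric = 2L,
    stop("unknown method: ", method)
  )
  role_code <- switch(role, search = 0L, validation = 1L,
                      stop("unknown seed role: ", role))
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(root_seed) %% m) * 48271 %% m
  s <- (s + n * 69621 + method_code * 16807 + role_code * 1299721) %% m
  as.integer(s)
}

# Shared argument check: methods accepted throughout the package.
match_ri_method <- function(method) {
  match.arg(method, c("parametric", "nonparametric"))
}
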
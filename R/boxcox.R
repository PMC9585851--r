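#' Fit a Box-Cox transform by profile maximum likelihood
#'
#' Finds the power parameter lambda maximizing the Box-Cox profile
#' log-likelihood over lambda in \[-5, 5\] with a bounded scalar
#' optimizer (tolerance 1e-5). Data containing zero or negative values
#' are first shifted by `1 - min(values)` so the transform is defined;
#' strictly positive data get shift 0. Near-ties in the likelihood are
#' broken toward the smaller |lambda|.
#'
#' @param values numeric vector; after the automatic shift all values
#'   must be strictly positive. Constant input is an error (the profile
#'   likelihood is undefined).
#' @return an object of class `boxcox_transform`: list with `lambda`,
#'   `shift` and `loglik` (profile log-likelihood at the optimum).
#' @seealso [boxcox_apply()], [boxcox_invert()]
#' @examples
#' boxcox_fit(rlnorm(200))   # lambda near 0
#' @export
boxcox_fit <- function(values) {
  x <- as.numeric(values)
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  if (max(x) == min(x))
    stop("Box-Cox likelihood undefined for constant data", call. = FALSE)
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  z <- x + shift
  lz <- log(z)
  slz <- sum(lz)
  n <- length(z)
  ll <- function(lam) {
    y <- if (lam == 0) lz else expm1(lam * lz) / lam
    v <- stats::var(y) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slz
  }
  opt <- stats::optimize(ll, interval = c(-5, 5), maximum = TRUE,
                         tol = 1e-5)
  lam <- opt$maximum
  best <- opt$objective
  # tie-break toward smaller |lambda| among near-equivalent optima
  for (cand in c(0, -lam)) {
    if (abs(cand) < abs(lam) && ll(cand) >= best - 1e-9 * max(1, abs(best))) {
      lam <- cand
      best <- ll(cand)
    }
  }
  structure(list(lambda = lam, shift = shift, loglik = best),
            class = "boxcox_transform")
}

#' Apply a fitted Box-Cox transform
#'
#' Computes `((x + shift)^lambda - 1) / lambda` (or `log(x + shift)` when
#' lambda = 0). The shifted values must be strictly positive.
#'
#' @param values numeric vector on the original scale.
#' @param transform a `boxcox_transform` from [boxcox_fit()].
#' @return numeric vector on the transformed scale.
#' @export
boxcox_apply <- function(values, transform) {
  stopifnot(inherits(transform, "boxcox_transform"))
  z <- as.numeric(values) + transform$shift
  if (any(z <= 0))
    stop("Box-Cox transform undefined: shifted values must be strictly ",
         "positive", call. = FALSE)
  lam <- transform$lambda
  if (lam == 0) log(z) else expm1(lam * log(z)) / lam
}

#' Invert a Box-Cox transform
#'
#' Exact inverse of [boxcox_apply()]: `(lambda * y + 1)^(1/lambda) - shift`
#' (or `exp(y) - shift` when lambda = 0). Inputs with
#' `lambda * y + 1 <= 0` are outside the transform's range.
#'
#' @param values numeric vector on the transformed scale.
#' @param transform a `boxcox_transform` from [boxcox_fit()].
#' @return numeric vector on the original scale.
#' @export
boxcox_invert <- function(values, transform) {
  stopifnot(inherits(transform, "boxcox_transform"))
  y <- as.numeric(values)
  lam <- transform$lambda
  if (lam == 0) return(exp(y) - transform$shift)
  u <- lam * y + 1
  if (any(u <= 0))
    stop("Box-Cox inverse undefined: lambda * y + 1 must be positive",
         call. = FALSE)
  exp(log(u) / lam) - transform$shift
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f, shift = %g\n",
              x$lambda, x$shift))
  invisible(x)
}
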
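# From-scratch oracles, independent of the package implementations they
# check: explicit sort-and-interpolate quantiles at plotting position
# k/(n+1), loop-based window statistics, and a grid-search Box-Cox
# profile likelihood.

oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- pp * (n + 1)
    if (h <= 1) return(s[1])
    if (h >= n) return(s[n])
    j <- floor(h)
    g <- h - j
    s[j] + g * (s[j + 1] - s[j])
  }, numeric(1))
}

oracle_moving_sum <- function(x, w) {
  k <- length(x) - w + 1
  vapply(seq_len(k), function(i) sum(x[i:(i + w - 1)]), numeric(1))
}

oracle_moving_median <- function(x, w) {
  k <- length(x) - w + 1
  vapply(seq_len(k), function(i) {
    s <- sort(x[i:(i + w - 1)])
    if (w %% 2 == 1) s[(w + 1) / 2]
    else (s[w / 2] + s[w / 2 + 1]) / 2
  }, numeric(1))
}

# Direct composition of the smoothing pipeline: flags -> window sums ->
# window medians -> first index where the median equals w.
oracle_first_stable <- function(flags, n_grid, w,
                                position = "run_start") {
  if (length(flags) < 2 * w - 1) return(NA_integer_)
  s <- oracle_moving_sum(flags, w)
  m <- oracle_moving_median(s, w)
  hits <- which(m == w)
  if (length(hits) == 0) return(NA_integer_)
  j <- hits[1]
  idx <- if (position == "run_start") j
         else min(j + 2 * (w - 1), length(n_grid))
  as.integer(n_grid[idx])
}

# Grid-search Box-Cox lambda maximizing the profile log-likelihood.
oracle_boxcox_lambda <- function(x, grid = seq(-3, 3, by = 0.001)) {
  n <- length(x)
  lx <- log(x)
  ll <- vapply(grid, function(lam) {
    y <- if (lam == 0) lx else (x^lam - 1) / lam
    v <- mean((y - mean(y))^2)
    -n / 2 * log(v) + (lam - 1) * sum(lx)
  }, numeric(1))
  grid[which.max(ll)]
}

# Large-sample standard error of the empirical p-th quantile of a
# distribution with density fun at that quantile.
quantile_se <- function(p, n, dens_at_q) {
  sqrt(p * (1 - p) / n) / dens_at_q
}

# Arbitrary Box-Cox transform object for round-trip checks.
make_transform <- function(lambda, shift = 0) {
  structure(list(lambda = lambda, shift = shift, loglik = NA_real_),
            class = "boxcox_transform")
}

# Small synthetic GCT file written in code (labelled synthetic; stands in
# for expression matrices the tests cannot download).
write_synthetic_gct <- function(path, genes, n_samples, seed = 1) {
  set.seed(seed)
  mat <- matrix(round(rlnorm(length(genes) * n_samples, 3, 0.3), 3),
                nrow = length(genes))
  header <- c("#1.2", paste(length(genes), n_samples, sep = "\t"))
  cols <- c("Name", "Description", paste0("SAMPLE_", seq_len(n_samples)))
  rows <- vapply(seq_along(genes), function(i) {
    paste(c(genes[i], paste0("desc_", i), mat[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(cols, collapse = "\t"), rows), path)
  invisible(mat)
}
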
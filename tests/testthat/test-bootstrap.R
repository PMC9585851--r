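test_that("resampling is deterministic given the seed", {
  set.seed(41)
  pop <- ri_population(rnorm(1000, 5))
  a <- resample_limits(pop, n = 50, B = 40, method = "nonparametric",
                       seed = 9)
  b <- resample_limits(pop, n = 50, B = 40, method = "nonparametric",
                       seed = 9)
  expect_identical(a, b)
  c <- resample_limits(pop, n = 50, B = 40, method = "nonparametric",
                       seed = 10)
  expect_false(identical(a$lowers, c$lowers))
})

test_that("constant populations give zero-width non-parametric limits", {
  pop <- ri_population(rep(7, 100))
  d <- resample_limits(pop, n = 30, B = 20, method = "nonparametric",
                       seed = 1)
  expect_true(all(d$lowers == 7) && all(d$uppers == 7))
  expect_true(all(d$widths == 0))
  expect_error(
    resample_limits(pop, n = 30, B = 20, method = "parametric", seed = 1),
    "degenerate")
})

test_that("bootstrap limit means recover the population quantiles", {
  set.seed(42)
  pop <- ri_population(rnorm(5000))
  d <- resample_limits(pop, n = 200, B = 500, method = "nonparametric",
                       seed = 7)
  expect_equal(mean(d$lowers), qnorm(0.025), tolerance = 0.1)
  expect_equal(mean(d$uppers), qnorm(0.975), tolerance = 0.1)
  expect_true(all(d$widths >= 0))
  expect_length(d$lowers, 500)
})

test_that("percentile CI matches the oracle and nests correctly", {
  x <- as.numeric(1:100)
  expect_equal(percentile_ci(x, 0.90), oracle_quantile(x, c(0.05, 0.95)),
               tolerance = 1e-12)
  cc <- percentile_ci(rep(2, 10))
  expect_identical(cc[1], cc[2])
  set.seed(43)
  s <- rnorm(500)
  ci90 <- percentile_ci(s, 0.90)
  ci50 <- percentile_ci(s, 0.50)
  expect_gte(ci50[1], ci90[1])
  expect_lte(ci50[2], ci90[2])
})

test_that("width summaries follow the package quantile convention", {
  set.seed(44)
  pop <- ri_population(rnorm(2000))
  d <- resample_limits(pop, n = 50, B = 100, method = "nonparametric",
                       seed = 2)
  d$widths <- as.numeric(1:1000)
  expect_equal(width_summary(d, "median"), 500.5)
  expect_equal(width_summary(d, "quintile1"),
               oracle_quantile(d$widths, 0.2))
  expect_equal(width_summary(d, "mean"), mean(1:1000))
  d$widths <- rep(3.5, 100)
  for (s in c("median", "mean", "quintile1", "quintile4"))
    expect_equal(width_summary(d, s), 3.5)
  expect_error(width_summary(d, "mode"), "unknown width summary")
})

test_that("upper-limit CI width exceeds lower-limit CI width on skewed data", {
  set.seed(45)
  pop <- generate_population(
    simulation_spec("lognormal", list(meanlog = 0, sdlog = 0.5),
                    pop_size = 5000, seed = 45))
  for (m in c("parametric", "nonparametric")) {
    d <- resample_limits(pop, n = 150, B = 200, method = m, seed = 5)
    ci_l <- percentile_ci(d$lowers)
    ci_u <- percentile_ci(d$uppers)
    expect_gt(ci_u[2] - ci_u[1], ci_l[2] - ci_l[1])
  }
})
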
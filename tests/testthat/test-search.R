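test_that("moving sum and moving median match hand-computed windows", {
  expect_equal(moving_sum(c(0, 0, 0, rep(1, 10)), 10), c(7, 8, 9, 10))
  expect_equal(moving_sum(rep(1, 15), 7), rep(7, 9))
  expect_equal(moving_sum(rep(0, 12), 10), rep(0, 3))
  expect_error(moving_sum(1:5, 10), "at least")

  expect_equal(moving_median(1:5, 3), c(2, 3, 4))
  expect_equal(moving_median(rep(4, 10), 10), 4)
  expect_equal(moving_median(c(1, 100, 2, 99), 2), c(50.5, 51, 50.5))
  expect_error(moving_median(1:5, 6), "at least")
})

test_that("window statistics agree with loop oracles on random sequences", {
  set.seed(51)
  for (i in 1:100) {
    len <- sample(10:120, 1)
    x <- rnorm(len)
    w <- sample(2:9, 1)
    expect_equal(moving_sum(x, w), oracle_moving_sum(x, w),
                 tolerance = 1e-12)
    expect_equal(moving_median(x, w), oracle_moving_median(x, w))
  }
})

test_that("first stable size matches the composed brute-force pipeline", {
  grid <- 40:2000
  expect_identical(first_stable_n(rep(1L, length(grid)), grid), 40L)
  expect_identical(first_stable_n(rep(0L, length(grid)), grid),
                   NA_integer_)

  # step-function flags: 0 below n = 100, 1 from there on
  flags <- as.integer(grid >= 100)
  expect_identical(first_stable_n(flags, grid, 10),
                   oracle_first_stable(flags, grid, 10))

  set.seed(52)
  for (i in 1:150) {
    len <- sample(5:200, 1)
    flags <- rbinom(len, 1, runif(1, 0.2, 0.9))
    ng <- seq(40, by = sample(c(1, 5), 1), length.out = len)
    for (w in c(2, 5, 10)) {
      for (pos in c("run_start", "window_end")) {
        expect_identical(first_stable_n(flags, ng, w, pos),
                         oracle_first_stable(flags, ng, w, pos))
      }
    }
  }
})

test_that("monotone flag prefixes map to the window-aligned estimate", {
  set.seed(53)
  for (i in 1:30) {
    len <- sample(30:150, 1)
    k <- sample(0:len, 1)
    flags <- c(rep(0L, len - k), rep(1L, k))
    ng <- seq(40, length.out = len)
    expect_identical(first_stable_n(flags, ng, 10),
                     oracle_first_stable(flags, ng, 10))
  }
})

test_that("evaluate_n produces coherent ratios and flags", {
  set.seed(54)
  pop <- ri_population(rnorm(3000, 10))
  ctl <- ri_control(B = 100, seed = 5)
  row <- evaluate_n(pop, 120, ctl, "nonparametric")
  expect_equal(row$R1, row$ci_lower_width / row$ri_width_summary)
  expect_equal(row$R2, row$ci_upper_width / row$ri_width_summary)
  expect_identical(row$flag,
                   as.integer(row$R1 < 0.2 && row$R2 < 0.2))
  expect_false(row$degenerate)

  # constant population: zero RI width is a failure, never a pass
  cpop <- ri_population(rep(4, 500))
  crow <- evaluate_n(cpop, 50, ctl, "nonparametric")
  expect_identical(crow$flag, 0L)
  expect_true(crow$degenerate)
  expect_true(is.na(crow$R1))
})

test_that("the full search is deterministic and honors early stopping", {
  pop <- generate_population(analyte_preset("ft4_like", pop_size = 1500,
                                            seed = 61))
  ctl <- ri_control(B = 60, step = 25, seed = 8, n_max = 1500)
  f1 <- ri_samplesize(pop, "parametric", ctl)
  f2 <- ri_samplesize(pop, "parametric", ctl)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)

  ctl_full <- ri_control(B = 60, step = 25, seed = 8, n_max = 1500,
                         early_stop = FALSE)
  f3 <- ri_samplesize(pop, "parametric", ctl_full)
  expect_identical(f1$fits$parametric$estimated_n,
                   f3$fits$parametric$estimated_n)
  expect_gte(nrow(f3$fits$parametric$trace),
             nrow(f1$fits$parametric$trace))
  # full-grid trace covers every candidate
  expect_identical(f3$fits$parametric$trace$n,
                   seq.int(40L, 1500L, by = 25L))
})

test_that("validation is an independent seeded re-run", {
  pop <- generate_population(analyte_preset("ft4_like", pop_size = 1500,
                                            seed = 62))
  ctl <- ri_control(B = 60, step = 25, seed = 8, n_max = 1500)
  fit <- ri_samplesize(pop, "parametric", ctl)
  f <- fit$fits$parametric
  expect_true(f$converged)
  v1 <- validate_at_n(fit$population, f$estimated_n, ctl, "parametric")
  expect_identical(unname(f$validation), unname(v1))
  # a different seed gives a different (but finite) pair
  v2 <- validate_at_n(fit$population, f$estimated_n, ctl, "parametric",
                      seed = 12345)
  expect_false(identical(v1, v2))
  expect_true(all(is.finite(v2)))
})

test_that("non-convergence is a sentinel result with a complete trace", {
  set.seed(63)
  pop <- ri_population(rlnorm(3000, 0, 1))
  ctl <- ri_control(n_min = 40, n_max = 60, step = 1, B = 50, seed = 2,
                    tukey = FALSE)
  fit <- ri_samplesize(pop, "nonparametric", ctl)
  f <- fit$fits$nonparametric
  expect_false(f$converged)
  expect_true(is.na(f$estimated_n))
  expect_identical(f$trace$n, 40:60)
  expect_true(all(is.na(f$validation)))
})

test_that("the estimate is non-increasing in the pass threshold", {
  pop <- generate_population(analyte_preset("tt3_like", pop_size = 2000,
                                            seed = 64))
  ests <- vapply(c(0.1, 0.2, 0.3), function(thr) {
    ctl <- ri_control(B = 80, step = 10, seed = 4, threshold = thr,
                      tukey = FALSE)
    coef(ri_samplesize(pop, "parametric", ctl))[["parametric"]]
  }, numeric(1))
  expect_true(all(diff(ests) <= 0))
})

test_that("window-end reporting maps 2(w-1) grid steps past run start", {
  grid <- seq(40L, 400L, by = 5L)
  flags <- as.integer(grid >= 150)
  a <- first_stable_n(flags, grid, 10, "run_start")
  b <- first_stable_n(flags, grid, 10, "window_end")
  expect_identical(b - a, 2L * 9L * 5L)
})
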
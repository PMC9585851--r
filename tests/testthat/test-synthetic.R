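test_that("presets hit their target coefficients of variation", {
  cvs <- c(tsh_like = 35.0, ft3_like = 6.0, ft4_like = 7.7,
           tt3_like = 9.4, tt4_like = 6.4)
  for (p in names(cvs)) {
    pop <- generate_population(analyte_preset(p, pop_size = 10000,
                                              seed = 71))
    cv <- 100 * sd(pop$values) / mean(pop$values)
    expect_lt(abs(cv - cvs[[p]]) / cvs[[p]], 0.10)
  }
})

test_that("generation is deterministic and shape-faithful", {
  spec <- analyte_preset("tsh_like", pop_size = 2000, seed = 72)
  a <- generate_population(spec)
  b <- generate_population(spec)
  expect_identical(a$values, b$values)
  # right skew of the lognormal preset
  x <- a$values
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0)
  # normal preset is roughly symmetric
  y <- generate_population(analyte_preset("ft3_like", pop_size = 10000,
                                          seed = 73))$values
  expect_lt(abs(mean((y - mean(y))^3) / sd(y)^3), 0.15)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_spec("normal", list(mean = 1, sd = -1)),
               "positive")
  expect_error(simulation_spec("normal", list(mean = 1)), "missing")
  expect_error(simulation_spec("mixture",
                               list(mean1 = 0, sd1 = 1, mean2 = 2,
                                    sd2 = 1, weight = 1.2)),
               "weight")
  expect_error(simulation_spec("normal", list(mean = 0, sd = 1),
                               pop_size = 50))
})

test_that("analytic intervals match closed forms and numeric inversion", {
  sn <- simulation_spec("normal", list(mean = 0, sd = 1), 100)
  ri <- true_ri(sn)
  expect_equal(c(ri$lower, ri$upper), c(-1, 1) * qnorm(0.975),
               tolerance = 1e-6)

  sl <- simulation_spec("lognormal", list(meanlog = 0, sdlog = 0.5), 100)
  ril <- true_ri(sl)
  expect_equal(c(ril$lower, ril$upper),
               exp(c(-1, 1) * qnorm(0.975) * 0.5), tolerance = 1e-6)

  sg <- simulation_spec("gamma", list(shape = 3, rate = 2), 100)
  rig <- true_ri(sg)
  # independent root-finding oracle on the gamma CDF
  oracle <- vapply(c(0.025, 0.975), function(p) {
    uniroot(function(x) pgamma(x, 3, 2) - p, c(1e-8, 50),
            tol = 1e-10)$root
  }, numeric(1))
  expect_equal(c(rig$lower, rig$upper), oracle, tolerance = 1e-6)

  # a mixture with identical components collapses to its normal
  sm <- simulation_spec("mixture",
                        list(mean1 = 5, sd1 = 2, mean2 = 5, sd2 = 2,
                             weight = 0.3), 100)
  rim <- true_ri(sm)
  expect_equal(c(rim$lower, rim$upper), qnorm(c(0.025, 0.975), 5, 2),
               tolerance = 1e-6)
})

test_that("bimodal mixture quantiles agree with a large-sample check", {
  sm <- simulation_spec("mixture",
                        list(mean1 = 0, sd1 = 1, mean2 = 6, sd2 = 1.5,
                             weight = 0.6),
                        pop_size = 200000, seed = 74)
  ri <- true_ri(sm)
  x <- generate_population(sm)$values
  emp <- ri_quantile(x, c(0.025, 0.975))
  expect_equal(c(ri$lower, ri$upper), emp, tolerance = 0.05)
})

test_that("both estimators recover the true interval on large samples", {
  spec <- analyte_preset("tsh_like", pop_size = 100000, seed = 75)
  pop <- generate_population(spec)
  truth <- true_ri(spec)
  sdlog <- spec$params$sdlog
  dens_lo <- dlnorm(truth$lower, spec$params$meanlog, sdlog)
  dens_hi <- dlnorm(truth$upper, spec$params$meanlog, sdlog)
  se_lo <- quantile_se(0.025, spec$pop_size, dens_lo)
  se_hi <- quantile_se(0.975, spec$pop_size, dens_hi)
  for (f in list(parametric_ri, nonparametric_ri)) {
    ri <- f(pop$values)
    expect_lt(abs(ri$lower - truth$lower), 3 * se_lo)
    expect_lt(abs(ri$upper - truth$upper), 3 * se_hi)
  }
})

test_that("populations round-trip through the delimited writer/reader", {
  pop <- generate_population(analyte_preset("ft4_like", pop_size = 200,
                                            seed = 76))
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_analyte_table(path, "ft4_like")
  expect_equal(back$values, pop$values, tolerance = 1e-12)
})
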
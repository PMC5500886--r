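test_that("posterior mode finds the dominant density peak", {
  expect_equal(posterior_mode(rep(3.7, 200)), 3.7)
  withr::with_seed(1, {
    x <- rnorm(10000)
    expect_lt(abs(posterior_mode(x)), 0.1)
    # bimodal mixture: mode near the dominant component, not the mean
    y <- c(rnorm(9000, 0, 0.1), rnorm(1000, 5, 0.1))
    expect_lt(abs(posterior_mode(y)), 0.2)
    expect_gt(abs(mean(y) - posterior_mode(y)), 0.3)
  })
})

test_that("posterior mode approximates the median for symmetric samples", {
  withr::with_seed(4, {
    x <- rnorm(10000, 2, 1)
    expect_equal(posterior_mode(x), median(x), tolerance = 0.05)
  })
})

test_that("HPD interval is the shortest window of sorted samples", {
  expect_equal(unname(hpd_interval(1:100, 0.95)), c(1, 95))  # tie-break low
  expect_equal(unname(hpd_interval(rep(2.5, 150))), c(2.5, 2.5))
  withr::with_seed(2, {
    x <- rexp(10000)
    ci <- hpd_interval(x, 0.95)
    # analytic 95% HPD of Exp(1) is [0, -log(0.05)] ~ [0, 2.996]
    expect_lt(abs(ci["lower"] - 0), 0.02)
    expect_lt(abs(ci["upper"] - 2.996), 0.15)
    # width is monotone non-decreasing in mass
    widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                     function(m) diff(unname(hpd_interval(x, m))), 1.0)
    expect_true(all(diff(widths) >= 0))
  })
  expect_error(hpd_interval(1:200, 1.2), "mass")
})

test_that("pMCMC is a floored, capped two-sided sign probability", {
  expect_equal(pmcmc(rep(1, 1000)), 0.002)
  expect_equal(pmcmc(c(rep(1, 500), rep(-1, 500))), 1)
  expect_equal(pmcmc(c(rep(1, 900), rep(-1, 100))), 0.2)
  expect_equal(pmcmc(rep(0, 500)), 1)  # all-zero: no sign evidence
  withr::with_seed(3, {
    x <- rnorm(1000, 1)
    expect_equal(pmcmc(2.7 * x), pmcmc(x))   # positive rescaling
    expect_equal(pmcmc(-x), pmcmc(x))        # sign flip swaps counts only
  })
})

test_that("between-level differences are per-iteration subtractions", {
  d <- fixed_effect_difference(c(1, 2, 3), c(0, 1, 1))
  expect_equal(attr(d, "samples"), c(1, 1, 2))
  same <- fixed_effect_difference(1:5, 1:5)
  expect_equal(same$pmcmc, 1)
  withr::with_seed(5, {
    sep <- fixed_effect_difference(rnorm(1000, 30), rnorm(1000, 0))
    expect_equal(sep$pmcmc, 0.002)
  })
  expect_error(fixed_effect_difference(1:3, 1:4), "aligned")
})

test_that("phylogenetic heritability is the per-iteration variance share", {
  h <- phylo_heritability(rep(75, 200), rep(25, 200))
  expect_equal(h$posterior_mode, 75)
  expect_equal(phylo_heritability(rep(0, 200), rep(10, 200))$posterior_mode, 0)
  expect_error(phylo_heritability(c(1, 0), c(1, 0)), "zero")
})

test_that("correlations from covariance matrices hit the closed cases", {
  const <- array(rep(c(4, 2, 2, 4), 100), dim = c(2, 2, 100))
  expect_equal(unique(correlation_from_cov(const)), 0.5)
  diags <- array(rep(c(3, 0, 0, 7), 50), dim = c(2, 2, 50))
  expect_equal(unique(correlation_from_cov(diags)), 0)
  bnd <- array(rep(c(1, -1, -1, 1), 50), dim = c(2, 2, 50))
  expect_equal(unique(correlation_from_cov(bnd)), -1)
  # invariance under separate positive rescaling of each trait
  withr::with_seed(6, {
    mats <- replicate(200, {
      L <- matrix(rnorm(4), 2)
      L %*% t(L) + diag(2) * 0.1
    })
    D <- diag(c(3, 0.2))
    scaled <- array(apply(mats, 3, function(m) D %*% m %*% D), dim = dim(mats))
    expect_equal(correlation_from_cov(scaled), correlation_from_cov(mats))
  })
})

test_that("correlation difference test reports HPD and strict exceedance", {
  eq <- correlation_difference_test(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(eq$proportion_a_greater, 0)  # ties do not count
  tw <- correlation_difference_test(c(0.5, 0.6), c(0.1, 0.2))
  expect_equal(attr(tw$diff, "samples"), c(0.4, 0.4))
  expect_equal(tw$proportion_a_greater, 1)
  withr::with_seed(8, {
    ex <- correlation_difference_test(runif(10000, -1, 1), runif(10000, -1, 1))
    expect_equal(ex$proportion_a_greater, 0.5, tolerance = 0.02)
  })
  expect_error(correlation_difference_test(1:3, 1:4), "aligned")
})

test_that("Gelman-Rubin PSRF follows its defining formula", {
  withr::with_seed(9, {
    x <- rnorm(500)
    expect_equal(gelman_rubin(list(x, x)), sqrt(499 / 500), tolerance = 1e-12)
    far <- list(rnorm(1000, 0), rnorm(1000, 10))
    expect_gt(gelman_rubin(far), 5)
  })
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
})

test_that("Geweke z-score separates stationary chains from drifting ones", {
  withr::with_seed(10, {
    expect_lt(abs(geweke(rnorm(2000))), 2)
    drift <- seq(0, 10, length.out = 2000) + rnorm(2000, 0, 0.5)
    expect_gt(abs(geweke(drift)), 2)
  })
  expect_equal(geweke(rep(1, 500)), 0)
  expect_error(geweke(rnorm(100)), "short")
})
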
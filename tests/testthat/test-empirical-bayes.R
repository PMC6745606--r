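# Gamma mixed model for squared z-values: likelihood identities, quadrature
# stability, fitting, and confidence intervals.

test_that("the shape-1/2 Gamma likelihood is the scaled chi-square(1)
           likelihood", {
  set.seed(505)
  z2 <- rchisq(30, df = 1)
  d <- data.frame(study_id = "s1", z2 = z2)
  # g = 0, sigma = 0: z^2 ~ chi-square(1) exactly
  expect_equal(-negloglik_conditional(0, 0, d),
               sum(dchisq(z2, df = 1, log = TRUE)), tolerance = 1e-10)
  # mean m: z^2 ~ m * chi-square(1)
  for (m in c(0.5, 1, 2)) {
    expect_equal(-negloglik_conditional(m - 1, 0, d),
                 sum(dchisq(z2 / m, df = 1, log = TRUE) - log(m)),
                 tolerance = 1e-10)
  }
})

test_that("sigma -> 0 continuity: the quadrature likelihood approaches the
           collapsed marginal one", {
  d <- simulate_zdataset(n_studies = 10, n_per_study = 8, g = 1, sigma = 0.3,
                         seed = 21)
  at0 <- negloglik_conditional(1, 0, d)
  near0 <- negloglik_conditional(1, 1e-6, d, n_quad = 30)
  expect_equal(near0, at0, tolerance = 1e-6)
})

test_that("doubling the quadrature order barely moves the log-likelihood", {
  d <- simulate_zdataset(n_studies = 15, n_per_study = 10, g = 1.2, sigma = 1,
                         seed = 31)
  for (par in list(c(1.2, 1), c(0.8, 0.4), c(2, 0.1))) {
    l20 <- negloglik_conditional(par[1], par[2], d, n_quad = 20)
    l40 <- negloglik_conditional(par[1], par[2], d, n_quad = 40)
    expect_equal(l20, l40, tolerance = 1e-6)
  }
})

test_that("likelihood prefers the generating parameters over a perturbed g", {
  wins <- 0L
  for (seed in 1:10) {
    d <- simulate_zdataset(n_studies = 40, n_per_study = 12, g = 1,
                           sigma = 0.5, seed = 1000 + seed)
    if (negloglik_conditional(1, 0.5, d) < negloglik_conditional(2.2, 0.5, d))
      wins <- wins + 1L
  }
  expect_gte(wins, 8L)  # majority of replicates
})

test_that("invalid data and parameters are rejected", {
  d <- data.frame(study_id = "s1", z2 = c(1, 2))
  expect_error(negloglik_conditional(-1.5, 0, d), "positive")
  expect_error(negloglik_conditional(1, 0,
               data.frame(study_id = "s1", z2 = c(1, 0))), "z2")
  expect_error(negloglik_conditional(1, 0, data.frame(x = 1)), "study_id")
  expect_error(fit_conditional(d), "studies")  # needs >= 2 studies
})

test_that("marginal fit is the moment estimator with cluster-robust CI", {
  d <- data.frame(study_id = rep(c("a", "b"), each = 3), z2 = rep(1, 6))
  expect_equal(fit_marginal(d)$g, 0)
  # law of large numbers at g = 1: mean(z2) near 2
  big <- simulate_zdataset(n_studies = 100, n_per_study = 100, g = 1,
                           sigma = 0, seed = 77)
  fm <- fit_marginal(big)
  se_mean <- sd(big$z2) / sqrt(nrow(big))
  expect_lt(abs(fm$g - 1), 3 * se_mean)
  expect_true(fm$ci_g[1] < fm$g && fm$g < fm$ci_g[2])
  # single study: robust CI unavailable, flagged, no error
  one <- fit_marginal(data.frame(study_id = "s", z2 = c(1, 2, 3)))
  expect_true(all(is.na(one$ci_g)))
  expect_match(one$ci_flag, "single study")
})

test_that("conditional fit recovers parameters and agrees with the marginal
           fit when the data carry no between-study heterogeneity", {
  d0 <- simulate_zdataset(n_studies = 50, n_per_study = 12, g = 1, sigma = 0,
                          seed = 55)
  fc <- fit_conditional(d0, ci = "wald")
  fm <- fit_marginal(d0)
  expect_true(fc$converged)
  expect_lt(fc$sigma, 0.15)
  expect_equal(fc$g, fm$g, tolerance = 1e-3)
  # heterogeneous data: point estimate lands near the truth
  d1 <- simulate_zdataset(n_studies = 50, n_per_study = 12, g = 1,
                          sigma = 0.5, seed = 56)
  f1 <- fit_conditional(d1, ci = "wald")
  expect_true(f1$converged)
  expect_lt(abs(f1$g - 1), 0.35)
  expect_true(is.finite(f1$trunc_mass) && f1$trunc_mass < 0.05)
})

test_that("profile likelihood interval brackets the estimate and nests with
           the level", {
  d <- simulate_zdataset(n_studies = 30, n_per_study = 12, g = 1, sigma = 0.4,
                         seed = 66)
  fit <- fit_conditional(d, ci = "wald")
  p50 <- profile_ci_g(d, fit, level = 0.50)
  p95 <- profile_ci_g(d, fit, level = 0.95)
  expect_true(p95$low <= p50$low && p50$high <= p95$high)
  expect_true(p50$low <= fit$g && fit$g <= p50$high)
  expect_identical(p95$flag, "two-sided")
})
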
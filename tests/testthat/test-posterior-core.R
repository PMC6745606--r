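# Conjugate posterior, sign probability, credible intervals, conditional
# coverage and p-value conversions under the N(0, g*se^2) prior.

test_that("shrink_posterior matches the quadrature posterior oracle", {
  set.seed(101)
  for (k in 1:100) {
    b <- runif(1, -5, 5); se <- runif(1, 0.2, 3); g <- runif(1, 0.1, 10)
    post <- shrink_posterior(b, se, g)
    orc <- oracle_posterior(b, se, g)
    expect_equal(post$mean, orc$mean, tolerance = 1e-8)
    expect_equal(post$sd, orc$sd, tolerance = 1e-8)
  }
})

test_that("default posterior shrinks halfway with sd se/sqrt(2)", {
  post <- shrink_posterior(2, 1)
  expect_equal(post$mean, 1)
  expect_equal(post$sd, 1 / sqrt(2))
  expect_equal(shrink_posterior(0, 3)$mean, 0)
  expect_equal(shrink_posterior(0, 3)$sd, 3 / sqrt(2))
  # flat-prior limit
  post <- shrink_posterior(2, 1, g = 1e6)
  expect_equal(post$mean, 2, tolerance = 1e-5)
  expect_equal(post$sd, 1, tolerance = 1e-5)
})

test_that("input validation rejects nonpositive se/g and bad p", {
  expect_error(shrink_posterior(1, 0), "se")
  expect_error(shrink_posterior(1, -1), "se")
  expect_error(shrink_posterior(1, 1, g = 0), "g")
  expect_error(credible_interval(1, 1, level = 1), "level")
  expect_error(credible_interval(1, 1, level = 0), "level")
  expect_error(p_to_absz(0), "p")
  expect_error(p_to_absz(1.2), "p")
  expect_error(coverage_vs_pvalue(0), "p")
})

test_that("sign_probability matches half-line posterior mass and is monotone", {
  expect_equal(sign_probability(0, 1), 0.5)
  # frozen oracle value: posterior mass of (0, Inf) at b = 1.96, se = 1, g = 1
  expect_equal(sign_probability(1.96, 1), 0.9171158, tolerance = 1e-7)
  expect_equal(sign_probability(1.96, 1),
               oracle_posterior(1.96, 1, 1)$p_positive, tolerance = 1e-10)
  # antisymmetry / complement rule
  expect_equal(sign_probability(-1, 1), 1 - sign_probability(1, 1))
  # strictly increasing in b
  b <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(sign_probability(b, 1)) > 0))
})

test_that("credible interval carries exactly its nominal posterior mass", {
  set.seed(202)
  for (k in 1:20) {
    b <- runif(1, -5, 5); se <- runif(1, 0.2, 3)
    g <- runif(1, 0.2, 5); level <- runif(1, 0.5, 0.99)
    ci <- credible_interval(b, se, g, level)
    post <- shrink_posterior(b, se, g)
    mass <- pnorm((ci$high - post$mean) / post$sd) -
      pnorm((ci$low - post$mean) / post$sd)
    expect_equal(mass, level, tolerance = 1e-12)
  }
  # default case: b/2 +/- 1.96 * se/sqrt(2), checked against quadrature
  ci <- credible_interval(2, 1)
  orc <- oracle_posterior(2, 1, 1)
  expect_equal(orc$mass_in(ci$low, ci$high), 0.95, tolerance = 1e-9)
  expect_equal(ci$low, 1 - qnorm(0.975) / sqrt(2))
  # symmetry at b = 0
  ci0 <- credible_interval(0, 1)
  expect_equal(ci0$low, -ci0$high)
})

test_that("credible interval endpoints scale linearly with (b, se)", {
  base <- credible_interval(1.3, 0.7, g = 2, level = 0.9)
  for (c in c(0.5, 2, 7)) {
    scaled <- credible_interval(c * 1.3, c * 0.7, g = 2, level = 0.9)
    expect_equal(scaled$low, c * base$low, tolerance = 1e-12)
    expect_equal(scaled$high, c * base$high, tolerance = 1e-12)
  }
})

test_that("conditional coverage of the Wald interval matches quadrature and
           declines with significance", {
  # posterior mass of [b - 1.96 se, b + 1.96 se] via quadrature oracle
  zc <- qnorm(0.975)
  for (b in c(0, 1, 1.96, 3)) {
    orc <- oracle_posterior(b, 1, 1)
    expect_equal(conditional_coverage(b, 1),
                 orc$mass_in(b - zc, b + zc), tolerance = 1e-9)
  }
  expect_equal(conditional_coverage(0, 1), 0.9944, tolerance = 1e-4)
  expect_equal(conditional_coverage(1.96, 1), 0.917, tolerance = 1e-3)
  # strictly decreasing in |b| at g = 1
  b <- seq(0, 5, by = 0.25)
  expect_true(all(diff(conditional_coverage(b, 1)) < 0))
  # flat-prior limit: 0.95 for any b
  expect_equal(conditional_coverage(2.7, 1, g = 1e8), 0.95, tolerance = 1e-6)
  expect_equal(conditional_coverage(0, 1, g = 1e8), 0.95, tolerance = 1e-6)
})

test_that("coverage_vs_pvalue is consistent with conditional_coverage and
           monotone in p", {
  expect_equal(coverage_vs_pvalue(1), conditional_coverage(0, 1))
  expect_equal(coverage_vs_pvalue(0.05), 0.917, tolerance = 1e-3)
  p <- c(0.001, 0.01, 0.05, 0.2, 0.5, 1)
  expect_true(all(diff(coverage_vs_pvalue(p)) > 0))
})

test_that("p_to_absz inverts the two-sided normal p-value", {
  # frozen values from the root-finding oracle
  expect_equal(p_to_absz(0.001), 3.2905, tolerance = 1e-4)
  expect_equal(p_to_absz(0.05), oracle_absz(0.05), tolerance = 1e-9)
  expect_equal(p_to_absz(1), 0)
  # identity p_to_absz(2*pnorm(-z)) = z on [0, 10]
  z <- seq(0, 10, by = 0.5)
  expect_equal(p_to_absz(2 * pnorm(-z)), z, tolerance = 1e-10)
})

test_that("implied standard error reconstructs |b|/|z|", {
  expect_equal(implied_se(2, 0.05), 2 / oracle_absz(0.05), tolerance = 1e-9)
  expect_equal(implied_se(-2, 0.05), implied_se(2, 0.05))
  expect_equal(implied_se(3.29, 0.001), 1, tolerance = 1e-3)
  expect_error(implied_se(0, 0.05), "undefined")
  expect_error(implied_se(2, 1), "p")
})

test_that("prior-data conflict flags p < 0.001 with a ~2% prior tail", {
  res <- prior_conflict(c(0.0005, 0.001, 0.5))
  expect_equal(res$conflict, c(TRUE, FALSE, FALSE))  # strict inequality
  # frozen value of 2*pnorm(-3.2905/sqrt(2)) from the normal-CDF oracle
  expect_equal(res$tail_prob[1], 0.0199784, tolerance = 1e-5)
  # a wider prior makes large |z| less surprising: bigger tail probability
  expect_gt(prior_conflict(0.5, g = 1)$tail_prob[1],
            prior_conflict(0.5, g = 0.25)$tail_prob[1])
})
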
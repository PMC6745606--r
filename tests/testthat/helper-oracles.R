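# Independent numerical oracles used across the test files.  These
# deliberately avoid the closed forms implemented in R/: posteriors are
# formed by direct quadrature of prior times likelihood, z-values by root
# finding on the normal CDF.

# Posterior moments/probabilities under the N(0, g*se^2) prior by direct
# quadrature of the unnormalized posterior density.
oracle_posterior <- function(b, se, g) {
  dens <- function(beta) dnorm(beta, 0, sqrt(g) * se) * dnorm(b, beta, se)
  Z <- integrate(dens, -Inf, Inf, rel.tol = 1e-13)$value
  m <- integrate(function(x) x * dens(x), -Inf, Inf, rel.tol = 1e-13)$value / Z
  v <- integrate(function(x) (x - m)^2 * dens(x), -Inf, Inf,
                 rel.tol = 1e-13)$value / Z
  p_pos <- integrate(dens, 0, Inf, rel.tol = 1e-13)$value / Z
  mass_in <- function(lo, hi)
    integrate(dens, lo, hi, rel.tol = 1e-13)$value / Z
  list(mean = m, sd = sqrt(v), p_positive = p_pos, mass_in = mass_in)
}

# |z| with two-sided normal p-value p, by root finding (not qnorm).
oracle_absz <- function(p) {
  if (p == 1) return(0)
  uniroot(function(z) 2 * pnorm(-z) - p, c(0, 40), tol = 1e-12)$root
}

# Monte-Carlo mean of |N(mu, sigma^2)| with its standard error.
oracle_folded_mc <- function(mu, sigma, n = 1e6) {
  x <- abs(rnorm(n, mu, sigma))
  list(mean = mean(x), se = sd(x) / sqrt(n))
}
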
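# Exact normal-normal conjugate inference under the N(0, g * se^2) prior.
#
# Throughout, B is an approximately normal, unbiased estimator of a
# regression coefficient beta with known standard error se, and the prior on
# beta is N(0, g * se^2).  With g = 1 (the default) the posterior given
# B = b is N(b/2, se^2/2), the sign probability is Phi(b / (sqrt(2) se)),
# and the marginal distribution of z = B/se is N(0, 2).

.check_se <- function(se) {
  if (!is.numeric(se) || any(!is.finite(se)) || any(se <= 0))
    stop("`se` must be a positive finite number", call. = FALSE)
}

.check_g <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("`g` must be a single positive finite number", call. = FALSE)
}

.check_b <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b)))
    stop("`b` must be finite numeric", call. = FALSE)
}

.check_p <- function(p, allow_one = TRUE) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) ||
      (allow_one && any(p > 1)) || (!allow_one && any(p >= 1)))
    stop("`p` must be a two-sided p-value in (0, 1", if (allow_one) "]" else ")",
         call. = FALSE)
}

#' Conjugate posterior under the default shrinkage prior
#'
#' Given an unbiased, normally distributed estimate `b` with standard error
#' `se`, and the zero-mean normal prior with variance `g * se^2`, returns the
#' exact conjugate posterior of the coefficient, which is normal with mean
#' `b * g / (g + 1)` and standard deviation `se * sqrt(g / (g + 1))`.  At the
#' default `g = 1` this is N(b/2, se^2/2): the estimate is shrunk halfway to
#' zero and the posterior sd is `se / sqrt(2)`.
#'
#' @param b Numeric vector of coefficient estimates.
#' @param se Positive numeric vector of standard errors (recycled with `b`).
#' @param g Ratio of prior variance to `se^2`; a single positive number.
#'   Default 1.
#' @return A data frame with columns `mean` and `sd`, one row per estimate.
#' @examples
#' shrink_posterior(2, 1)          # mean 1, sd 1/sqrt(2)
#' shrink_posterior(2, 1, g = 1e6) # essentially the flat-prior N(2, 1)
#' @export
shrink_posterior <- function(b, se, g = 1) {
  .check_b(b); .check_se(se); .check_g(g)
  n <- max(length(b), length(se))
  b <- rep_len(b, n); se <- rep_len(se, n)
  data.frame(mean = b * g / (g + 1), sd = se * sqrt(g / (g + 1)))
}

#' Posterior probability that the coefficient is positive
#'
#' Returns P(beta > 0 | B = b) under the N(0, g * se^2) prior, i.e.
#' `pnorm(post_mean / post_sd)`.  For `g = 1` this is
#' `pnorm(b / (sqrt(2) * se))`.  The complement rule
#' P(beta < 0 | B = b) = 1 - P(beta > 0 | B = b) holds exactly.
#'
#' @inheritParams shrink_posterior
#' @return Numeric vector of probabilities.
#' @examples
#' sign_probability(1.96, 1)  # about 0.917
#' @export
sign_probability <- function(b, se, g = 1) {
  post <- shrink_posterior(b, se, g)
  stats::pnorm(post$mean / post$sd)
}

#' Central credible interval under the shrinkage prior
#'
#' Central posterior interval `post_mean +/- z * post_sd` with
#' `z = qnorm((1 + level)/2)`.  At `g = 1` and `level = 0.95` this is
#' `b/2 +/- 1.96 * se/sqrt(2)`: half the width of the standard Wald interval,
#' centered at the shrunk estimate, and carrying exactly 95% posterior mass.
#'
#' @inheritParams shrink_posterior
#' @param level Credibility level in (0, 1). Default 0.95.
#' @return A data frame with columns `low` and `high`.
#' @examples
#' credible_interval(2, 1)  # 1 +/- 1.96/sqrt(2)
#' @export
credible_interval <- function(b, se, g = 1, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  post <- shrink_posterior(b, se, g)
  z <- stats::qnorm((1 + level) / 2)
  data.frame(low = post$mean - z * post$sd, high = post$mean + z * post$sd)
}

#' Conditional coverage of the standard Wald interval
#'
#' Posterior probability, under the N(0, g * se^2) prior, that the
#' coefficient lies in the usual 95% confidence interval
#' `[b - 1.96 se, b + 1.96 se]` given the observed `b`.  For `g = 1` this is
#' `pnorm(b/(sqrt(2) se) + 1.96 sqrt(2)) - pnorm(b/(sqrt(2) se) - 1.96 sqrt(2))`,
#' which is about 0.994 at b = 0 and declines below 0.95 as |b| grows: the
#' more significant the estimate, the poorer the Bayesian coverage of the
#' frequentist interval.  As `g -> Inf` (flat prior) the coverage is 0.95 for
#' every b.
#'
#' @inheritParams shrink_posterior
#' @param conf Nominal confidence level of the Wald interval being assessed.
#'   Default 0.95, i.e. the half-width is `qnorm(0.975) * se`.
#' @return Numeric vector of posterior coverage probabilities.
#' @examples
#' conditional_coverage(0, 1)     # about 0.994
#' conditional_coverage(1.96, 1)  # about 0.917
#' @export
conditional_coverage <- function(b, se, g = 1, conf = 0.95) {
  post <- shrink_posterior(b, se, g)
  n <- nrow(post)
  b <- rep_len(b, n); se <- rep_len(se, n)
  zc <- stats::qnorm((1 + conf) / 2)
  stats::pnorm((b + zc * se - post$mean) / post$sd) -
    stats::pnorm((b - zc * se - post$mean) / post$sd)
}

#' Conditional coverage as a function of the two-sided p-value
#'
#' Maps a two-sided p-value to `|b|/se = |qnorm(p/2)|` and evaluates
#' [conditional_coverage()] there; this is the natural x-axis for plotting
#' the decline of coverage with increasing significance.
#'
#' @param p Two-sided p-values in (0, 1].
#' @inheritParams conditional_coverage
#' @return Numeric vector of posterior coverage probabilities.
#' @examples
#' coverage_vs_pvalue(c(1, 0.05, 0.001))
#' @export
coverage_vs_pvalue <- function(p, g = 1, conf = 0.95) {
  .check_p(p)
  conditional_coverage(p_to_absz(p), 1, g = g, conf = conf)
}

#' Convert a two-sided p-value to an absolute z-value
#'
#' Returns `|z| = |qnorm(p/2)|`, the absolute z-value whose two-sided normal
#' p-value is `p`, so that `2 * pnorm(-|z|) == p` to machine precision.
#'
#' @param p Two-sided p-values in (0, 1].
#' @return Nonnegative numeric vector.
#' @examples
#' p_to_absz(0.05)   # 1.96
#' p_to_absz(0.001)  # 3.29
#' @export
p_to_absz <- function(p) {
  .check_p(p)
  abs(stats::qnorm(p / 2))
}

#' Implied standard error from an estimate and its p-value
#'
#' When a paper reports an estimate and a two-sided p-value but no standard
#' error, `|b| / |z|` with `|z| = |qnorm(p/2)|` reconstructs an "implied"
#' standard error.  It may be larger than the true estimated standard error,
#' depending on how the p-value was computed (e.g. from a t reference).
#'
#' @param b Nonzero coefficient estimates.
#' @param p Two-sided p-values in (0, 1); `p = 1` gives `|z| = 0` and is an
#'   error.
#' @return Positive numeric vector.
#' @examples
#' implied_se(2, 0.05)  # about 1.02
#' @export
implied_se <- function(b, p) {
  .check_b(b)
  .check_p(p, allow_one = FALSE)
  if (any(b == 0))
    stop("implied standard error is undefined for b = 0", call. = FALSE)
  abs(b) / p_to_absz(p)
}

#' Prior-data conflict flag for small p-values
#'
#' The default prior should not be used when a two-sided p-value below 0.001
#' is observed: that corresponds to `|z| > 3.29`, an event with probability
#' about 2% under the g = 1 prior (the marginal of z = B/se is normal with
#' variance g + 1), so such an observation is in conflict with the prior.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param g Prior variance ratio; default 1.
#' @param threshold Conflict threshold on the p-value; default 0.001.
#' @return A data frame with columns `conflict` (logical, `p < threshold`)
#'   and `tail_prob` (the marginal probability of the conflict event under
#'   the prior, `2 * pnorm(-z_thr / sqrt(g + 1))`, identical across rows).
#' @examples
#' prior_conflict(c(0.0005, 0.5))
#' @export
prior_conflict <- function(p, g = 1, threshold = 0.001) {
  .check_p(p); .check_g(g)
  z_thr <- abs(stats::qnorm(threshold / 2))
  data.frame(conflict = p < threshold,
             tail_prob = 2 * stats::pnorm(-z_thr / sqrt(g + 1)))
}
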
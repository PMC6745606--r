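# Folded-normal machinery: magnitude overestimation under the flat prior
# (type M error) and the corresponding quantities under the shrinkage prior.

#' Mean of the folded normal distribution
#'
#' If X ~ N(mu, sigma^2) then |X| has the folded normal distribution with
#' mean `|mu| + sqrt(2/pi) * sigma * exp(-mu^2 / (2 sigma^2))
#' - 2 |mu| * pnorm(-|mu| / sigma)`.  By Jensen's inequality this is always
#' at least `|mu|`.
#'
#' For `|mu|/sigma > 38` both correction terms underflow double precision
#' and `|mu|` is returned directly.
#'
#' @param mu Mean of the underlying normal (any real).
#' @param sigma Standard deviation of the underlying normal (positive).
#' @return Nonnegative numeric vector, `E|X|`.
#' @examples
#' folded_mean(0, 1)  # sqrt(2/pi), about 0.798
#' @export
folded_mean <- function(mu, sigma) {
  .check_b(mu)
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive finite", call. = FALSE)
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  r <- abs(mu) / sigma
  out <- abs(mu) + sqrt(2 / pi) * sigma * exp(-r^2 / 2) -
    2 * abs(mu) * stats::pnorm(-r)
  out[r > 38] <- abs(mu)[r > 38]
  out
}

#' Frequentist bias of |B| as an estimator of |beta|
#'
#' For fixed beta, |B| has the folded normal distribution and overestimates
#' |beta| on average: the bias `E|B| - |beta|` is largest at beta = 0, where
#' it equals `sqrt(2/pi) * se`, about `0.8 * se`, and decays to zero as
#' |beta| moves away from the origin.
#'
#' @param beta True coefficient value(s).
#' @param se Standard error of the estimator (positive).
#' @return Nonnegative numeric vector of biases.
#' @examples
#' magnitude_bias(0, 1)  # sqrt(2/pi)
#' magnitude_bias(3, 1)  # nearly 0
#' @export
magnitude_bias <- function(beta, se) {
  folded_mean(beta, se) - abs(beta)
}

#' Flat-prior posterior mean of the coefficient magnitude
#'
#' Under the improper flat prior the posterior of beta given B = b is
#' N(b, se^2), so the posterior mean of |beta| is the folded-normal mean at
#' (b, se).  It is always at least |b| -- the Bayes estimate of the
#' magnitude under the flat prior is even larger than the already positively
#' biased |B|, which is why the flat prior inflates magnitudes.
#'
#' @inheritParams shrink_posterior
#' @return Nonnegative numeric vector.
#' @export
flat_posterior_magnitude_mean <- function(b, se) {
  folded_mean(b, se)
}

#' Shrinkage-prior posterior mean of the coefficient magnitude
#'
#' Posterior mean of |beta| under the N(0, g * se^2) prior: the posterior is
#' normal (see [shrink_posterior()]), so this is exactly the folded-normal
#' mean at the posterior mean and sd.  For any (b, se) at g = 1 it is
#' smaller than the flat-prior value.
#'
#' @inheritParams shrink_posterior
#' @return Nonnegative numeric vector.
#' @examples
#' shrunk_posterior_magnitude_mean(0, 1)  # sqrt(2/pi)/sqrt(2)
#' @export
shrunk_posterior_magnitude_mean <- function(b, se, g = 1) {
  post <- shrink_posterior(b, se, g)
  folded_mean(post$mean, post$sd)
}
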
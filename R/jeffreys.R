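# Numeric Jeffreys prior for theta = |beta| when the sign carries a
# Bernoulli(1/2) prior: the observation B then follows a two-component
# normal mixture in theta, the Fisher information has no closed form, and
# the Jeffreys prior sqrt(I(theta)) is computed by quadrature.

.check_theta_se <- function(theta, se) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0))
    stop("`theta` must be nonnegative finite", call. = FALSE)
  .check_se(se)
}

#' Two-component mixture density of the estimate given the magnitude
#'
#' With theta = |beta| and a fair coin on the sign of beta, the density of
#' the estimate B is
#' `(1/2se) * (dnorm((b + theta)/se) + dnorm((b - theta)/se))`.
#' At theta = 0 the components coincide and the density is N(0, se^2).
#'
#' @param b Numeric vector of observation points.
#' @param theta Magnitude parameter (single nonnegative number).
#' @param se Standard error (single positive number).
#' @return Numeric vector of densities.
#' @export
mixture_density <- function(b, theta, se) {
  .check_theta_se(theta, se)
  stopifnot(length(theta) == 1L, length(se) == 1L)
  0.5 * (stats::dnorm(b, -theta, se) + stats::dnorm(b, theta, se))
}

#' Score function of the mixture model in theta
#'
#' Exact derivative of the log mixture density with respect to theta:
#' `(-(b+theta) phi((b+theta)/se) + (b-theta) phi((b-theta)/se)) /
#'  (se^2 (phi((b+theta)/se) + phi((b-theta)/se)))`.
#' The 1/se^2 constant comes from differentiating the normal kernels; it
#' matters because the Fisher information squares the score.  Computed with
#' log-space mixture weights so that it stays accurate when one component
#' underflows (large theta/se).
#'
#' @inheritParams mixture_density
#' @return Numeric vector, the score at each `b`.
#' @export
score_theta <- function(b, theta, se) {
  .check_theta_se(theta, se)
  stopifnot(length(theta) == 1L, length(se) == 1L)
  la <- stats::dnorm(b, -theta, se, log = TRUE)  # component centered at -theta
  lc <- stats::dnorm(b, +theta, se, log = TRUE)
  m <- pmax(la, lc)
  wa <- exp(la - m); wc <- exp(lc - m)
  tot <- wa + wc
  (-(b + theta) * wa + (b - theta) * wc) / (se^2 * tot)
}

#' Fisher information for the magnitude under sign uncertainty
#'
#' `E_theta[score^2]`, computed by adaptive quadrature of
#' `score_theta(b)^2 * mixture_density(b)` over
#' `b` in `[-(theta + 10 se), theta + 10 se]` (neglected tail mass below
#' 1e-12) to absolute tolerance 1e-9.  The information is 0 at theta = 0
#' (the score vanishes identically) and rises to the location-model value
#' `1/se^2` once the components separate (theta >> se); in between, the sign
#' uncertainty destroys information.
#'
#' @inheritParams mixture_density
#' @return A single nonnegative number.
#' @examples
#' fisher_info(0, 1)      # 0
#' fisher_info(6, 1)      # about 1
#' @export
fisher_info <- function(theta, se) {
  .check_theta_se(theta, se)
  stopifnot(length(theta) == 1L, length(se) == 1L)
  if (theta == 0) return(0)
  f <- function(b) score_theta(b, theta, se)^2 * mixture_density(b, theta, se)
  lim <- theta + 10 * se
  # symmetric integrand: integrate the positive half and double
  q <- tryCatch(
    stats::integrate(f, 0, lim, abs.tol = 5e-10, rel.tol = 1e-9,
                     subdivisions = 1000L),
    error = function(e)
      stop("Fisher information quadrature failed (theta = ", theta,
           ", se = ", se, "): ", conditionMessage(e), call. = FALSE))
  2 * q$value
}

#' Jeffreys prior for the magnitude, on a grid
#'
#' Evaluates the (unnormalized, improper) Jeffreys prior
#' `sqrt(I(theta))` on a uniform grid over `[0, theta_max]`.  The prior is 0
#' at theta = 0, rises over a region of width a few `se`, and is flat at
#' `1/se` beyond -- i.e. under the sign-magnitude parameterization the
#' Jeffreys rule no longer yields the uniform prior but one even more
#' dispersed, favoring larger magnitudes.
#'
#' @param theta_max Upper end of the grid (positive).
#' @param n_points Number of grid points (at least 2).
#' @param se Standard error (single positive number).
#' @return A data frame with columns `theta`, `value` (unnormalized
#'   `sqrt(I)`), and `se`.
#' @examples
#' head(jeffreys_grid(4, 9, se = 1))
#' @export
jeffreys_grid <- function(theta_max, n_points, se) {
  stopifnot(is.numeric(theta_max), theta_max > 0,
            is.numeric(n_points), n_points >= 2)
  .check_se(se)
  theta <- seq(0, theta_max, length.out = as.integer(n_points))
  value <- vapply(theta, function(th) sqrt(fisher_info(th, se)), numeric(1))
  data.frame(theta = theta, value = value, se = se)
}
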
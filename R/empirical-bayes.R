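# Empirical-Bayes estimation of the prior variance ratio g from collections
# of published two-sided p-values.
#
# Hierarchical model: each study j has its own ratio g_j ~ N(g, sigma^2);
# within study j, beta_ij ~ N(0, g_j * se_ij^2) and B_ij ~ N(beta_ij,
# se_ij^2), so the z-value Z_ij = B_ij / se_ij is N(0, g_j + 1) given g_j,
# and Z_ij^2 is Gamma with shape 1/2 and mean g_j + 1.  Fitting this Gamma
# model with identity link, offset 1 and a Gaussian study effect estimates
# the population g; g = 1 corresponds to the default prior N(0, se^2).

.gh_cache <- new.env(parent = emptyenv())

.gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

.MEAN_FLOOR <- 1e-10  # Gamma mean below this is treated as infeasible

.check_zdata <- function(data, min_studies = 1L) {
  if (!is.data.frame(data) || !all(c("study_id", "z2") %in% names(data)))
    stop("`data` must be a data frame with columns study_id and z2",
         call. = FALSE)
  if (nrow(data) == 0L) stop("`data` has no rows", call. = FALSE)
  if (any(!is.finite(data$z2)) || any(data$z2 < 0))
    stop("z2 values must be finite and nonnegative", call. = FALSE)
  if (any(data$z2 == 0))
    stop("z2 = 0 (p-value of exactly 1) has unbounded Gamma(shape 1/2) ",
         "density and cannot be used for fitting", call. = FALSE)
  if (length(unique(data$study_id)) < min_studies)
    stop(sprintf("at least %d studies are required", min_studies),
         call. = FALSE)
  invisible(data)
}

# Per-study sufficient statistics: Gamma(shape 1/2, mean m) log-likelihood is
# n*a*log(a/m) - n*lgamma(a) + (a-1)*sum(log z2) - (a/m)*sum(z2), a = 1/2.
.study_stats <- function(data) {
  sid <- factor(data$study_id)
  list(n    = as.numeric(tapply(data$z2, sid, length)),
       s    = as.numeric(tapply(data$z2, sid, sum)),
       slog = as.numeric(tapply(log(data$z2), sid, sum)))
}

.gamma_ll <- function(m, n, s, slog) {
  # log-likelihood of one study's z2 at common mean m; -Inf if infeasible
  if (!is.finite(m) || m <= .MEAN_FLOOR) return(-Inf)
  a <- 0.5
  n * a * log(a / m) - n * lgamma(a) + (a - 1) * slog - (a / m) * s
}

# Adaptive Gauss-Hermite marginal log-likelihood of one study:
# log int exp(h(u)) du with h(u) = gamma_ll(g + sigma*u + 1) + log phi(u).
# The rule is centered and scaled at the integrand's mode (Laplace step) and
# its order is then doubled from n_quad until the value is stable to 1e-9
# (cap 320 nodes) -- small studies give skewed integrands for which a fixed
# low-order rule is not accurate enough.
.study_marg_ll <- function(g, sigma, n, s, slog, n_quad) {
  a <- 0.5
  h_vec <- function(u) {
    m <- g + sigma * u + 1
    ll <- rep(-Inf, length(u))
    ok <- is.finite(m) & m > .MEAN_FLOOR
    ll[ok] <- n * a * log(a / m[ok]) - n * lgamma(a) + (a - 1) * slog -
      (a / m[ok]) * s
    ll + stats::dnorm(u, log = TRUE)
  }
  u_min <- (.MEAN_FLOOR - 1 - g) / sigma   # feasibility: mean > floor
  lo <- max(u_min + 1e-9, -12); hi <- 12
  if (lo >= hi) return(-Inf)
  opt <- stats::optimize(h_vec, c(lo, hi), maximum = TRUE, tol = 1e-8)
  u_hat <- opt$maximum
  # curvature -> AGH scale, clamped against flat or spiky profiles
  eps <- 1e-4
  hv3 <- h_vec(c(max(u_hat - eps, lo), u_hat, min(u_hat + eps, hi)))
  h2 <- (hv3[1] - 2 * hv3[2] + hv3[3]) / eps^2
  s_hat <- if (is.finite(h2) && h2 < 0) 1 / sqrt(-h2) else 1
  s_hat <- min(max(s_hat, 1e-3), 5)
  eval_rule <- function(nq) {
    gh <- .gh_rule(nq)
    lw <- log(gh$w) + gh$x^2 + h_vec(u_hat + sqrt(2) * s_hat * gh$x)
    keep <- is.finite(lw)
    if (!any(keep)) return(-Inf)
    mx <- max(lw[keep])
    log(sqrt(2) * s_hat) + mx + log(sum(exp(lw[keep] - mx)))
  }
  nq <- as.integer(n_quad)
  val <- eval_rule(nq)
  repeat {
    nq2 <- min(2L * nq, 320L)
    val2 <- eval_rule(nq2)
    done <- (is.finite(val) && is.finite(val2) && abs(val2 - val) < 1e-9) ||
      nq2 >= 320L
    val <- val2; nq <- nq2
    if (done) break
  }
  val
}

#' Negative log-likelihood of the conditional Gamma mixed model
#'
#' Computes the negative marginal log-likelihood of the squared z-values
#' under the hierarchical model: within study j the z2 are Gamma with shape
#' 1/2 and mean `g + sigma * u_j + 1`, with `u_j` standard normal.  The
#' study-level integral is evaluated by adaptive Gauss-Hermite quadrature:
#' the rule is centered and scaled at the per-study mode and its order is
#' doubled from `n_quad` until the study log-likelihood is stable to 1e-9.
#' Random-effect values that
#' would make the Gamma mean nonpositive contribute zero likelihood, which
#' truncates the effect distribution to the feasible region.
#'
#' With `sigma = 0` the integral collapses and the value equals the
#' marginal (no random effect) Gamma log-likelihood exactly.
#'
#' @param g Population mean of the study-level variance ratios.
#' @param sigma Standard deviation of the study effects (nonnegative; a
#'   negative value is interpreted through its absolute value, since the
#'   likelihood is even in sigma).
#' @param data Data frame with columns `study_id` and `z2` (strictly
#'   positive squared z-values), e.g. from [to_zdataset()] or
#'   [simulate_zdataset()].
#' @param n_quad Starting number of Gauss-Hermite quadrature nodes
#'   (default 20); the rule is refined from there until stable.
#' @return A single number, the negative log-likelihood (`Inf` if the
#'   parameters leave no feasible mean anywhere).
#' @export
negloglik_conditional <- function(g, sigma, data, n_quad = 20) {
  .check_zdata(data)
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            n_quad >= 5)
  sigma <- abs(sigma)
  st <- .study_stats(data)
  if (sigma == 0) {
    if (g + 1 <= .MEAN_FLOOR)
      stop("g + 1 must be positive when sigma = 0", call. = FALSE)
    ll <- sum(vapply(seq_along(st$n), function(j)
      .gamma_ll(g + 1, st$n[j], st$s[j], st$slog[j]), numeric(1)))
    return(-ll)
  }
  ll <- sum(vapply(seq_along(st$n), function(j)
    .study_marg_ll(g, sigma, st$n[j], st$s[j], st$slog[j], n_quad),
    numeric(1)))
  -ll
}

.new_hier_fit <- function(g, sigma, ci_g, level, loglik, n_quad, converged,
                          method, n_studies, n_values, trunc_mass = NA_real_,
                          ci_flag = "two-sided") {
  structure(list(g = g, sigma = sigma, ci_g = ci_g, level = level,
                 loglik = loglik, n_quad = n_quad, converged = converged,
                 method = method, n_studies = n_studies, n_values = n_values,
                 trunc_mass = trunc_mass, ci_flag = ci_flag),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("Gamma mixed model fit (%s), %d z-values in %d studies\n",
              x$method, x$n_values, x$n_studies))
  cat(sprintf("  g (prior variance / se^2): %.3f  [%g%% CI %.3f, %.3f]\n",
              x$g, 100 * x$level, x$ci_g[1], x$ci_g[2]))
  cat(sprintf("  implied prior sd ratio sqrt(g): %.3f\n", sqrt(max(x$g, 0))))
  cat(sprintf("  sigma (between-study sd of g_j): %.3f\n", x$sigma))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n",
              x$loglik, x$converged))
  if (x$ci_flag != "two-sided")
    cat(sprintf("  note: CI is %s\n", x$ci_flag))
  if (is.finite(x$trunc_mass) && x$trunc_mass > 1e-6)
    cat(sprintf("  note: %.2g of the random-effect mass was truncated\n",
                x$trunc_mass))
  invisible(x)
}

#' Fit the conditional Gamma mixed model for the variance ratio g
#'
#' Maximum-likelihood fit of the hierarchical model described in
#' [negloglik_conditional()], over (g, sigma), by Nelder-Mead with three
#' starting points (the moment start `(mean(z2) - 1, 0.5)` plus two
#' perturbations) to guard against flat-likelihood plateaus.  The Gamma
#' shape is fixed at 1/2 throughout, as dictated by the chi-square(1)
#' distribution of a squared z-value.  The 95% confidence interval for g is
#' a profile-likelihood interval by default (Wald optional).
#'
#' @inheritParams negloglik_conditional
#' @param start Optional length-2 numeric `c(g, sigma)` starting value.
#' @param ci Interval type for g: `"profile"` (default) or `"wald"`.
#' @param level Confidence level, default 0.95.
#' @return An object of class `hier_fit` with elements `g`, `sigma`,
#'   `ci_g`, `loglik`, `converged`, `method = "conditional"`, `trunc_mass`
#'   (normal mass truncated to keep the Gamma mean positive at the fit).
#'   Non-convergence is reported through `converged = FALSE`, not an error.
#' @examples
#' d <- simulate_zdataset(n_studies = 20, n_per_study = 10, g = 1,
#'                        sigma = 0.5, seed = 1)
#' fit_conditional(d, ci = "wald")
#' @export
fit_conditional <- function(data, start = NULL, n_quad = 20,
                            ci = c("profile", "wald"), level = 0.95) {
  .check_zdata(data, min_studies = 2L)
  ci <- match.arg(ci)
  if (is.null(start)) start <- c(mean(data$z2) - 1, 0.5)
  stopifnot(length(start) == 2L, all(is.finite(start)))
  obj <- function(par) {
    v <- tryCatch(negloglik_conditional(par[1], par[2], data, n_quad),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(start,
                 start + c(0.5, 0.25),
                 c(max(start[1] - 0.5, -0.9), max(start[2] / 2, 0.05)))
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  g_hat <- best$par[1]; sig_hat <- abs(best$par[2])
  converged <- best$convergence == 0 && best$value < 1e9
  trunc_mass <- if (sig_hat > 0) stats::pnorm(-(g_hat + 1) / sig_hat) else 0
  fit <- .new_hier_fit(g = g_hat, sigma = sig_hat, ci_g = c(NA_real_, NA_real_),
                       level = level, loglik = -best$value, n_quad = n_quad,
                       converged = converged, method = "conditional",
                       n_studies = length(unique(data$study_id)),
                       n_values = nrow(data), trunc_mass = trunc_mass)
  if (!converged) return(fit)
  if (ci == "profile") {
    pc <- profile_ci_g(data, fit, level = level)
    fit$ci_g <- c(pc$low, pc$high); fit$ci_flag <- pc$flag
  } else {
    fit$ci_g <- .wald_ci_g(data, g_hat, sig_hat, n_quad, level)
  }
  fit
}

# Wald CI from a finite-difference Hessian of the negative log-likelihood
.wald_ci_g <- function(data, g, sigma, n_quad, level) {
  f <- function(p) negloglik_conditional(p[1], p[2], data, n_quad)
  hstep <- c(1e-4 * max(abs(g), 1), 1e-4 * max(sigma, 0.1))
  H <- matrix(0, 2, 2)
  p0 <- c(g, sigma)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- (f(p0 + ei + ej) - f(p0 + ei - ej) -
                f(p0 - ei + ej) + f(p0 - ei - ej)) / (4 * hstep[i] * hstep[j])
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se_g <- sqrt(V[1, 1])
  z <- stats::qnorm((1 + level) / 2)
  c(g - z * se_g, g + z * se_g)
}

#' Fit the marginal Gamma model (no random effect)
#'
#' Intercept-only Gamma model with shape 1/2, identity link and offset 1:
#' all z2 share mean `g + 1`, and the maximum-likelihood estimate is
#' `g_hat = mean(z2) - 1`.  The confidence interval uses cluster-robust
#' (by study) sandwich standard errors, so between-study correlation
#' inflates the interval even though the point estimate ignores it.
#'
#' @inheritParams negloglik_conditional
#' @param level Confidence level, default 0.95.
#' @return An object of class `hier_fit` with `method = "marginal"` and
#'   `sigma = 0`.  With fewer than 2 studies the robust CI is unavailable
#'   and flagged.
#' @export
fit_marginal <- function(data, level = 0.95) {
  .check_zdata(data)
  m_hat <- mean(data$z2)
  g_hat <- m_hat - 1
  ll <- -negloglik_conditional(g_hat, 0, data)
  n <- nrow(data)
  sid <- factor(data$study_id)
  J <- nlevels(sid)
  if (J >= 2L) {
    cl_sum <- tapply(data$z2 - m_hat, sid, sum)
    se_g <- sqrt(sum(cl_sum^2)) / n   # cluster-robust SE of the mean
    z <- stats::qnorm((1 + level) / 2)
    ci <- c(g_hat - z * se_g, g_hat + z * se_g)
    flag <- "two-sided"
  } else {
    ci <- c(NA_real_, NA_real_)
    flag <- "unavailable (single study)"
  }
  .new_hier_fit(g = g_hat, sigma = 0, ci_g = ci, level = level, loglik = ll,
                n_quad = 0L, converged = TRUE, method = "marginal",
                n_studies = J, n_values = n, trunc_mass = 0, ci_flag = flag)
}

#' Profile-likelihood confidence interval for g
#'
#' For a converged conditional fit, profiles the log-likelihood over sigma
#' at fixed g and finds the two points where twice the drop from the
#' maximum crosses the chi-square(1) quantile, by bracketing and root
#' finding (tolerance 1e-4).  If the profile never crosses on one side
#' (boundary or flat likelihood), a one-sided interval is returned with a
#' flag.
#'
#' @inheritParams negloglik_conditional
#' @param fit A converged `hier_fit` from [fit_conditional()].
#' @param level Confidence level in (0, 1).
#' @return A list with `low`, `high`, and `flag` (`"two-sided"` or which
#'   side is open).
#' @export
profile_ci_g <- function(data, fit, level = 0.95) {
  stopifnot(inherits(fit, "hier_fit"))
  if (!fit$converged) stop("profile CI requires a converged fit", call. = FALSE)
  if (fit$n_studies < 2L)
    return(list(low = -Inf, high = Inf, flag = "unavailable (single study)"))
  n_quad <- max(fit$n_quad, 20)
  sig_up <- max(4 * fit$sigma, 2)
  pll <- function(g) {
    o <- stats::optimize(function(s) {
      v <- tryCatch(negloglik_conditional(g, s, data, n_quad),
                    error = function(e) Inf)
      if (is.finite(v)) v else 1e10
    }, c(0, sig_up), tol = 1e-6)
    -o$objective
  }
  target <- fit$loglik - stats::qchisq(level, 1) / 2
  find_side <- function(dir) {
    step <- max(0.25, abs(fit$g) / 4)
    g_in <- fit$g
    for (k in 1:40) {
      g_out <- fit$g + dir * k * step
      if (g_out <= -0.999) { g_out <- -0.999 }
      v <- pll(g_out)
      if (v < target) {
        r <- stats::uniroot(function(g) pll(g) - target,
                            lower = min(g_in, g_out),
                            upper = max(g_in, g_out), tol = 1e-4)
        return(r$root)
      }
      g_in <- g_out
      if (g_out == -0.999) break
    }
    NA_real_
  }
  lo <- find_side(-1); hi <- find_side(+1)
  flag <- "two-sided"
  if (is.na(lo)) { lo <- -Inf; flag <- "one-sided (lower open)" }
  if (is.na(hi)) { hi <- Inf
    flag <- if (flag == "two-sided") "one-sided (upper open)" else "unbounded" }
  list(low = lo, high = hi, flag = flag)
}
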
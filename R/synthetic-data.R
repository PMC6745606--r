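# Synthetic study collections under the hierarchical model, and
# single-estimate draws under the normal-normal model, so every fitter and
# coverage claim can be exercised without external data.

#' Simulate a study collection of squared z-values
#'
#' Draws from the hierarchical model behind the empirical-Bayes fit: each
#' study receives its own variance ratio `g_j ~ N(g, sigma^2)`, truncated
#' to `g_j >= 0` by rejection (a prior variance cannot be negative; the
#' rejected mass is recorded as an attribute), and the study's z-values are
#' then `N(0, g_j + 1)`, returned squared.
#'
#' Defaults mirror a typical literature collection: 50 studies of about 12
#' usable p-values each, population ratio g = 1.28 with between-study sd
#' 0.5.
#'
#' @param n_studies Number of studies (default 50).
#' @param n_per_study Values per study: a single count or a vector of
#'   length `n_studies` (default 12).
#' @param g Population mean of the study-level variance ratios
#'   (default 1.28).
#' @param sigma Between-study sd of the ratios (nonnegative, default 0.5).
#' @param seed Integer seed.
#' @return Data frame with columns `study_id` and `z2`; attributes
#'   `g_j` (the study-level ratios actually used) and `rejection_rate`
#'   (fraction of g_j draws rejected as negative).
#' @examples
#' d <- simulate_zdataset(n_studies = 5, n_per_study = 4, seed = 1)
#' mean(d$z2)  # about g + 1
#' @export
simulate_zdataset <- function(n_studies = 50, n_per_study = 12, g = 1.28,
                              sigma = 0.5, seed) {
  stopifnot(is.numeric(n_studies), n_studies >= 1,
            is.numeric(n_per_study), all(n_per_study >= 1),
            length(n_per_study) %in% c(1L, as.integer(n_studies)),
            is.numeric(g), is.finite(g),
            is.numeric(sigma), sigma >= 0)
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n_studies <- as.integer(n_studies)
  n_per <- rep_len(as.integer(n_per_study), n_studies)
  g_j <- numeric(n_studies)
  n_rejected <- 0L
  for (j in seq_len(n_studies)) {
    repeat {
      draw <- stats::rnorm(1, g, sigma)
      if (draw >= 0) { g_j[j] <- draw; break }
      n_rejected <- n_rejected + 1L
      if (n_rejected > 1e6)
        stop("rejection sampling for g_j >= 0 is not terminating; ",
             "g is far below 0 relative to sigma", call. = FALSE)
    }
  }
  study_id <- rep(sprintf("study%03d", seq_len(n_studies)), times = n_per)
  z <- stats::rnorm(sum(n_per), 0, rep(sqrt(g_j + 1), times = n_per))
  out <- data.frame(study_id = study_id, z2 = z^2)
  attr(out, "g_j") <- g_j
  attr(out, "rejection_rate") <- n_rejected / (n_rejected + n_studies)
  out
}

#' Simulate coefficient/estimate pairs under the normal-normal model
#'
#' Draws `beta ~ N(0, g * se^2)` and `B | beta ~ N(beta, se^2)`, the model
#' under which the default prior is exactly calibrated.  Useful for
#' checking marginal coverage of the Wald interval, conditional coverage
#' curves, and sign-agreement rates against their closed forms.
#'
#' @param n Number of draws.
#' @param g Ratio of prior variance to `se^2` (default 1).
#' @param se_values Standard errors, recycled to length `n` (default 1).
#' @param seed Integer seed.
#' @return Data frame with columns `beta`, `b`, `se`.
#' @examples
#' d <- simulate_estimates(1000, seed = 2)
#' mean(abs(d$b - d$beta) < 1.96 * d$se)  # about 0.95
#' @export
simulate_estimates <- function(n, g = 1, se_values = 1, seed) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(g), g > 0,
            is.numeric(se_values), all(se_values > 0))
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  se <- rep_len(se_values, n)
  beta <- stats::rnorm(n, 0, sqrt(g) * se)
  b <- stats::rnorm(n, beta, se)
  data.frame(beta = beta, b = b, se = se)
}
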
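---
title: "Methods: a default shrinkage prior for regression coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a default shrinkage prior for regression coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defaultprior)
```

## The model and its assumptions

Everything in this package rests on one working assumption: we observe an
approximately normal, *unbiased* estimate $B$ of a regression coefficient
$\beta$ with *known* standard error $se$,
$$B \mid \beta \sim N(\beta, se^2).$$
This is the large-sample regime of M-estimation in linear and generalized
linear models (with or without random effects), GEE and quantile
regression; small-sample $t$ corrections are deliberately out of scope (the
difference is already negligible beyond roughly 40 degrees of freedom, and
the package would misstate its own precision if it pretended otherwise).

The default prior is
$$\beta \sim N(0, g \cdot se^2), \qquad g = 1 \text{ by default},$$
and conjugacy gives the posterior
$$\beta \mid B = b \sim N\!\Big(\frac{g}{g+1}\,b,\; \frac{g}{g+1}\,se^2\Big),$$
i.e. $N(b/2, se^2/2)$ at $g = 1$: shrink the estimate halfway to zero,
shrink the standard error by $\sqrt 2$. All posterior summaries
(`sign_probability`, `credible_interval`, `conditional_coverage`) are exact
normal-CDF expressions; no Monte Carlo is used anywhere in that module.

Why $g = 1$ specifically? Two independent arguments converge on it:

1. **Non-informativeness for the sign.** If $\beta \sim N(0, se^2)$, the
   marginal of $B$ is $N(0, 2se^2)$, so $P(\beta > 0 \mid B) =
   \Phi(B/(\sqrt 2\, se))$ is *exactly* standard uniform — the prior adds
   no information about the direction of the effect.
   `sign_uniformity_sim()` verifies this by simulation and a
   Kolmogorov–Smirnov test, and shows the uniformity breaks when the
   generating prior sd is misspecified (e.g. $2se$).
2. **Empirical plausibility.** Fitting the hierarchical model below to
   collections of published univariate $p$-values gives population
   estimates of $g$ close to 1 (see the empirical-Bayes section).

A note on rendering: informal statements of these results sometimes drop
the radicals (writing "sd $se/2$" for the posterior). The package
implements the exact conjugate algebra — posterior sd $se/\sqrt2$, sign
probability $\Phi(b/(\sqrt2\,se))$ — which is the only version under which
the uniformity property above actually holds.

## What the flat prior gets wrong

Under the improper flat prior the posterior is $N(b, se^2)$ and posterior
quantiles match one-sided confidence bounds, which is why the flat prior is
often called objective. But for the *magnitude* and the *sign*:

- $|B|$ has a folded normal distribution given $\beta$, with mean
  $|\beta| + \sqrt{2/\pi}\,se\,e^{-\beta^2/2se^2} -
  2|\beta|\Phi(-|\beta|/se) \ge |\beta|$ (Jensen). The bias peaks at
  $\beta = 0$ at $\sqrt{2/\pi}\,se \approx 0.8\,se$ (`magnitude_bias`).
  The flat-prior posterior mean of $|\beta|$ is the same formula evaluated
  at $(b, se)$ — *larger* than the already inflated $|b|$
  (`flat_posterior_magnitude_mean`). The shrinkage posterior, being
  normal, reuses the same folded-normal mean at the shrunk location/scale
  and is uniformly smaller at $g = 1$.
- Sign evidence: the flat-prior value $P(\operatorname{sgn}\beta =
  \operatorname{sgn} B \mid b) = \Phi(|b|/se)$ is an upper bound over
  *all* symmetric unimodal priors. `sign_agreement_prob()` checks any such
  prior by adaptive quadrature of prior × likelihood (absolute tolerance
  1e-12 on each panel, integrand truncated where the normal likelihood is
  below machine noise, i.e. beyond $10\,se$ from $b$). $b = 0$ is rejected
  rather than assigned a sign convention.

`conditional_coverage()` ties these together: under the default prior the
usual 95% Wald interval contains $\beta$ with posterior probability 0.994
at $p = 1$, 0.95 around $p \approx 0.11$, and ever less as $p$ shrinks —
significance is precisely where the frequentist interval is least
trustworthy as a credible interval.

## Jeffreys prior for the magnitude

Parameterization invariance (Jeffreys' rule) also selects the flat prior
for a location parameter — but only under smooth reparameterizations.
Splitting $\beta$ into a sign with a Bernoulli(1/2) prior and a magnitude
$\theta = |\beta|$ gives the mixture likelihood
$$f(b \mid \theta) = \tfrac{1}{2se}\,\phi\!\Big(\frac{b+\theta}{se}\Big) +
  \tfrac{1}{2se}\,\phi\!\Big(\frac{b-\theta}{se}\Big),$$
whose Fisher information $I(\theta) = E_\theta[\text{score}^2]$ has no
closed form. Numerical choices:

- The score is implemented as the exact derivative (the $1/se^2$ constant
  retained — it matters because $I$ squares the score), with log-space
  mixture weights so large $\theta/se$ does not underflow
  (`score_theta`; note the score is an *even* function of $b$, since the
  mixture density itself is even in $b$).
- $I(\theta)$ integrates score² × density over
  $[-(\theta + 10se), \theta + 10se]$ (neglected mass < 1e-12) with
  absolute tolerance 1e-9, exploiting the integrand's symmetry
  (`fisher_info`).
- The prior $\sqrt{I(\theta)}$ is improper and reported unnormalized on a
  uniform grid (`jeffreys_grid`). It is 0 at $\theta = 0$, rises over a
  few $se$, and flattens at $1/se$ (the location-model information once
  the components separate) — more dispersed than uniform, reinforcing
  that no standard objectivity criterion rescues the flat prior here.

## Empirical Bayes: estimating g from published p-values

Model: study $j$ carries its own ratio $g_j \sim N(g, \sigma^2)$; within
study $j$, $\beta_{ij} \sim N(0, g_j\,se_{ij}^2)$ and $B_{ij} \sim
N(\beta_{ij}, se_{ij}^2)$. Then $z_{ij} = B_{ij}/se_{ij} \sim
N(0, g_j + 1)$ given $g_j$, so $z_{ij}^2$ is Gamma with shape $\tfrac12$
and mean $g_j + 1$ (a scaled $\chi^2_1$; this identity is tested against
`dchisq`). Fitting the Gamma mixed model with identity link, offset 1 and
a Gaussian study effect estimates $g$; the shape is *fixed* at ½, never
estimated, because it is dictated by the $\chi^2_1$ distribution.

Implementation decisions, in the order they bit:

- **Identity-link positivity.** A Gaussian effect on an identity-link mean
  can push $g + \sigma u + 1$ negative. The likelihood treats the
  integrand as zero wherever the mean falls below 1e-10 — equivalent to
  truncating the effect distribution to the feasible region — and the fit
  reports the truncated normal mass as a diagnostic (`trunc_mass`). For
  the parameter ranges of interest ($g \approx 1$–$1.3$,
  $\sigma \lesssim 0.6$) this mass is of order 1e-5.
- **Quadrature.** Each study's integral uses adaptive Gauss–Hermite:
  Laplace centering and scaling at the integrand's mode, then the rule
  order doubles from `n_quad` (default 20) until the study log-likelihood
  is stable to 1e-9 (cap 320 nodes). The refinement step exists because
  small studies give visibly skewed integrands for which a fixed 20-node
  rule is only ~1e-4 accurate. Consequence: the total log-likelihood is
  insensitive (< 1e-6) to the choice of starting order.
- **Optimization.** Nelder–Mead over $(g, \sigma)$ from the moment start
  $(\overline{z^2} - 1,\, 0.5)$ plus two perturbations; the likelihood is
  even in $\sigma$, so the optimizer roams freely and $|\hat\sigma|$ is
  reported. Non-convergence yields `converged = FALSE`, never an
  exception.
- **Confidence interval for g.** The interval construction is a design
  choice: profile likelihood by default (root-finding the $\chi^2_1$
  cutoff to 1e-4, with one-sided flags when the profile never crosses),
  Wald from a finite-difference Hessian as an option. Profile is
  preferred because $g$ behaves like a variance-ratio parameter and its
  likelihood is asymmetric near the $\sigma = 0$ boundary.
- **$z^2 = 0$** (a p-value of exactly 1) has unbounded Gamma(shape ½)
  density and is rejected with an explicit error rather than clamped.
- **No censoring correction.** Collections exclude $p < 0.001$, which
  truncates the $z^2$ distribution; the likelihood is deliberately fitted
  without an adjustment for this, replicating standard practice for such
  collections. An adjusted likelihood is out of scope.
- **Scale of g.** The model places $g$ on the *variance* scale (prior
  variance $g\,se^2$, $z$-variance $g_j + 1$). Collection-based estimates
  near 1.28 are sometimes loosely described as an sd ratio; on the
  variance-scale model that corresponds to $\sqrt{1.28} \approx 1.13$.
  The fit prints both $g$ and $\sqrt g$ so the two readings cannot be
  conflated.

The marginal model (`fit_marginal`) drops the random effect: the MLE is
the moment estimator $\hat g = \overline{z^2} - 1$, with cluster-robust
(by study) sandwich standard errors. At $\hat\sigma \to 0$ the two fits
agree to 1e-3 in $\hat g$, which the tests check.

Data ingestion (`read_collection`) accepts CSV with `study_id`, `p_value`
and optional flags; rows with textual summaries ("NS", "<0.01") or $p
\notin (0,1]$ are reported by row number, never silently dropped. The
eligibility filters drop intercepts (a zero-centered prior is wrong for
them), F-test p-values (no signed $z$), secondary outcomes
(`outcome_rank > 1`; when the column is absent all rows pass), and
$p < 0.001$ — *strictly* below, so the boundary value $p = 0.001$ is
kept; rounded p-values are taken at face value with no interval-censoring
treatment. Conversion to $z^2$ uses $|z| = |\Phi^{-1}(p/2)|$; discarding
the sign is harmless because only symmetric priors are entertained.

## The synthetic-data generator

`simulate_zdataset()` draws from the hierarchical model itself; its
defaults are the study conditions the rest of the package is validated
under: 50 studies of 12 values (the shape of a realistic literature
collection of ~600 p-values), population ratio $g = 1.28$ with
between-study sd $\sigma = 0.5$. No collection reports a $\sigma$
estimate, so 0.5 is a deliberate, admittedly arbitrary choice that makes
between-study heterogeneity visible without dominating; it is not
calibrated to any dataset. One knowing deviation from the model on paper:
$g_j$ is truncated at 0 by rejection sampling (a negative prior variance
cannot generate data), and the rejection rate is recorded as an
attribute. For the default parameters the truncated mass is
$\Phi(-1.28/0.5) \approx 0.005$.

What the generator does *not* emulate: publication bias, p-hacking,
rounding of reported p-values, censoring at $p < 0.001$, non-normal
estimators, or correlated coefficients within a study. Parameter-recovery
results on synthetic data therefore validate the estimator under its own
model — they say nothing about how inflated real literature z-values are.

At the design size (50 × 12) the estimator is consistent but not sharp:
$\sigma$ in particular is weakly identified and individual fits can
collapse $\hat\sigma$ to 0; the acceptance-level claim is about the
*median* $\hat g$ over 20 seeds lying in [1.1, 1.5] when the truth is
1.28.

## Problem sizes and tolerances used in validation

Chosen to make every claim checkable in a few tens of seconds on one CPU:
conjugate formulas against quadrature oracles at 1e-8; credible-interval
mass to 1e-12; folded-normal means against 1e6-draw Monte Carlo within 4
standard errors; the sign-evidence bound on a 63-case (3 families × 3
scales × 7 estimates) grid at 1e-6; KS uniformity at n = 1e5; Fisher
information endpoints at relative error 1e-3 and the score against finite
differences at 1e-6; conditional coverage against binned simulation
(8×10⁵ draws) within 4 binomial standard errors; g-recovery over 20
seeds at the 50 × 12 design.

## Limitations

- Known-$se$ normality is assumed throughout; no $t$ corrections, no
  multivariate/joint priors across coefficients.
- The uniqueness of $N(0, se^2)$ as the prior making the sign probability
  uniform is plausible but unproven; the package tests only the stated
  direction.
- Posterior inference *under* the folded Jeffreys prior is not provided —
  only the prior itself is computed.
- The empirical-Bayes estimate inherits every bias of its input
  collection (selective reporting, favorable dichotomization), which
  argues for treating collection-based $\hat g$ as an upper bound and
  $g = 1$ as the conservative default.
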
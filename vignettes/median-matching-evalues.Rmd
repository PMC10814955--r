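---
title: "Invariant e-values from median matching priors: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant e-values from median matching priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmatch)
```

## The problem

The Full Bayesian Significance Test (FBST) measures the evidence in favor
of a sharp hypothesis $H_0\colon \psi = \psi_0$ through the *e-value*: one
minus the posterior mass of the *tangential set*, the set of parameter
values whose posterior surprise exceeds the largest surprise attained on
the null set.  In its original form the FBST needs the posterior over the
full parameter $\theta = (\psi, \lambda)$, a reference function $r(\theta)$,
a constrained optimization and a $d$-dimensional integration — and the
result changes under reparameterization of the nuisance $\lambda$.

`evmatch` implements a pseudo-posterior route that needs none of that.  For
a scalar parameter of interest $\psi$ it builds

$$\pi^*(\psi \mid y) \;\propto\; \exp\Bigl\{\ell_p(\psi) + \int m(\psi,
\hat\lambda_\psi)\, d\psi\Bigr\},$$

where $\ell_p$ is the profile log-likelihood and $m$ is the *median
correction*: the $O(1)$ adjustment to the (profile) score whose root is a
median-unbiased, reparameterization-equivariant estimator.  The implied
prior — the *median matching prior* — is exactly the prior whose posterior
mode equals that estimator, so the maximum a posteriori (MAP) estimate
transports exactly through monotone interest-respecting transformations.
Because the construction absorbs the reference function into the prior, no
reference needs to be elicited, and no integration over $\lambda$ ever
happens.

## Modified score equations

For a scalar model with score $\ell_\theta$, expected information
$i(\theta)$ and third score cumulant $\kappa_3(\theta) =
E(\ell_\theta^3)$, the median-modified score is

$$t(\theta) = \ell_\theta(\theta) + m(\theta), \qquad
m(\theta) = \frac{\kappa_3(\theta)}{6\, i(\theta)}.$$

In a canonical exponential family this is $K'''/(6K'')$, the derivative of
$\log i(\theta)^{1/6}$: the median matching prior is $i(\theta)^{1/6}$.
The mean-bias-reducing (Firth) variant uses
$m_F = (E(\ell_\theta^3) + E(\ell_{\theta\theta}\ell_\theta))/(2 i)$,
whose prior is Jeffreys' $i(\theta)^{1/2}$ — the *predictive matching
prior*.  The sign convention above is certified by two oracles built into
the test suite: the canonical prior exponents $1/6$ and $1/2$, and the
median-unbiasedness of the exponential-scale estimator
$\tilde\theta = n\bar y/(n - 1/3)$, whose $P(\tilde\theta \le \theta_0)$
is $0.5$ to within Monte Carlo error because the median of a
Gamma$(n)$ variable is approximately $n - 1/3$.  A
`sign_convention = "as-displayed"` flag exposes the opposite convention
for auditing.

With nuisance parameters the correction becomes
$m(\psi, \hat\lambda_\psi) = -\kappa_{1\psi} + \kappa_{3\psi}/(6\kappa_{2\psi})$
with $\kappa_{k\psi}$ the cumulants of the profile score
$\ell_p'(\psi)$.  We read the grouping as "recentre by the mean, then
shift by the skewness term" because (i) it reduces exactly to the scalar
case when $\kappa_1 = 0$ and (ii) it is the Cornish–Fisher median
expansion of the profile score.  The cumulants are estimated by a
parametric bootstrap at $(\psi, \hat\lambda_\psi)$ — self-contained and
model-agnostic — with a closed-form shortcut for canonical families
without nuisance.  Each dataset replicate refits the constrained nuisance
maximizer, and the third cumulant uses the unbiased $k$-statistic.

## e-value computation routes

* **Exact grid** (`evalue_exact_1d`): the pseudo-posterior is normalized
  on a grid, the tangential set located by superlevel-set crossing with
  spline-refined boundaries, and its mass integrated by adaptive
  quadrature on a density spline.
* **Wald-type** (`evalue_wald`): $2\{1 - \Phi(|\psi_0 - \tilde\psi|\,
  i(\psi_0)^{1/2})\}$, differing from the classical first-order
  approximation only in the location estimate.
* **Score-type** (`evalue_score`): $2\{1 - \Phi(|t(\psi_0)|\,
  i(\psi_0)^{-1/2})\}$.  Because $t/\sqrt{i}$ transforms as a scalar under
  monotone reparameterization, this e-value is *exactly* invariant.
* **Tail-area** (`evalue_tailarea`): the third-order route through the
  Laplace marginal posterior, the profile likelihood root $r_p$, the
  Bayesian correction factor $q_B$ and the modified root
  $r_B^* = r_p + \log(q_B/r_p)/r_p$, for a user-supplied prior and
  reference over the full parameter.

The asymptotic null law of the e-value is $V(c) = Q(d-h, Q^{-1}(d, c))$ in
terms of chi-square distribution functions (`evalue_null_cdf`); for a
scalar parameter it is the identity, so e-values are asymptotically
uniform under the null — the property the calibration harness
(`run_null_calibration`) measures via Kolmogorov–Smirnov distances.

## Supported models

Canonical one-parameter exponential families built from the cumulant
function (`model_expfam`, with `model_exponential_rate` and
`model_poisson_canonical` ready-made); gamma/exponential scale models with
known shape (`model_gamma_mean`, `model_exponential_scale`); the
skew-normal shape family $2\varphi(y)\Phi(y\theta)$ (`model_skewnorm`,
location 0 and scale 1 fixed, as the density form implies); logistic
regression with a bound design matrix (`model_logistic`); and a bivariate
regression with equicorrelated paired errors
(`model_bivariate_regression`), interest on the correlation $\rho$.
`reparam_model` transports any scalar model through a monotone map with
exact chain-rule derivatives so equivariance can be checked to machine
precision.

## Numerical choices

* **Skew-normal integrals.** The correction needs
  $E\{(Y\varphi(Y\theta)/\Phi(Y\theta))^k\}$, $k = 2, 3$.  The ratio
  $\varphi/\Phi$ is evaluated in log space (`pnorm(log.p = TRUE)` switches
  to an asymptotic Mills-ratio expansion in the far lower tail), and the
  quadrature is split at $0$ and at $\pm 1/(1+|\theta|)$ because the
  integrand kinks at the origin and concentrates on a $1/\theta$ scale for
  large shape values.  Target relative accuracy $10^{-8}$.
* **Posterior grids.** Default 801 points over $\hat\psi \pm 8$ standard
  errors; the grid doubles its half-width (and point count, up to 4001)
  while the outermost boundary mass exceeds $10^{-4}$, stopping at 64
  standard errors — weak-identification posteriors (a monotone likelihood
  with a slowly decaying matching prior) can carry genuinely heavy tails.
  The mode is refined against the continuous log-kernel, not the grid, so
  it matches the estimating-equation root to $\sim 10^{-8}$ even when the
  kernel is nearly flat.
* **Correction integration.** The correction is integrated by cumulative
  Simpson.  Cheap closed-form corrections are evaluated exactly at every
  Simpson node; bootstrap corrections are cached at 41 $\psi$ nodes and
  splined, with *constant* extrapolation outside the cached range (linear
  extrapolation of an $O(1)$ quantity fabricates spurious growth) and a
  degeneracy guard that drops nodes whose simulated profile-score
  distribution collapses to a point mass with rare outliers (sd/MAD
  ratio above 10, the signature of separation-saturated designs),
  densifying inside the healthy window when needed.
* **Root finding.** Bracket expansion by doubling from the centre,
  Brent refinement at tolerance $10^{-12}$ on the equation scale; when
  the MLE is infinite the search (and the posterior grid) is centred on
  the Jeffreys-penalized profile maximizer, which is always finite.
* **Tail-area singular window.** $r_B^*$ is $0/0$ at $\hat\psi$; inside
  $|r_p| < 0.05$ it is replaced by a cubic fitted through four flanking
  points, keeping the root continuous through the maximum (flagged in the
  result).
* **Predictive matching with nuisance parameters.** The construction is
  the profile of the Jeffreys-penalized log-likelihood
  $\max_\lambda\{\ell + \tfrac12 \log\lvert i\rvert\}$, consistent with
  the prior $\lvert i(\beta)\rvert^{1/2}$ in logistic regression; its
  $\psi$-derivative is taken by the envelope identity (inner maximizer
  frozen) so optimizer noise enters only at second order.
* **ABC.** Rejection sampling with the paper-style budget ($10^5$ draws,
  best 5% kept).  The default distance uses decile order statistics
  standardized by the observed scale; the evidence-table harness uses
  estimating-function summaries (the per-observation score at four points
  flanking the MLE), which are near-sufficient and give much sharper ABC
  posteriors at the same budget.  Improper priors are truncated to a wide
  range (default $[-2, 25]$ for the skew-normal studies, generously
  covering the likelihood support) and sampled by inverse CDF on a grid.
  MAPs from ABC draws use a Gaussian KDE with Silverman bandwidth,
  refined by local optimization.

## What the synthetic generators emulate

The seeded generators reproduce the study designs: skew-normal samples at
shape $\theta_0 = 3$ with $n \in \{20, 30, 50, 200\}$; an all-positive
skew-normal sample, the canonical monotone-likelihood case in which the
flat-prior posterior is improper while every matching-prior posterior has
a finite mode; the bivariate regression draw at $\rho_0 = 0.95$, $n = 20$
with standard-normal covariates and $\beta = (1, 2, -1)$, $\sigma^2 = 1$
(covariate and coefficient values are this package's choice — only the
error structure and sample size are prescribed by the design); and a
quasi-completely separated binary-outcome design with $n = 79$, one binary
covariate aligned with the response on its positive stratum and two
continuous covariates, mimicking the structure of the endometrial cancer
grade dataset (HG \~ NV + PI + EH).  That clinical dataset itself is not
bundled; `endometrial_analysis()` accepts a user-supplied CSV with those
columns and otherwise runs on the labelled-synthetic stand-in.  Passing
tests on these fixtures demonstrates the machinery — divergence detection,
finite corrected estimates, proper posteriors, invariant e-values — not
agreement with any particular clinical estimate.

## Problem sizes used in tests

Monte Carlo sizes are scaled for a deterministic, quick test suite, as a
design choice of this package: profile-cumulant bootstraps use 150–1500
replicates in tests (the package default is 2000); the calibration study
runs 2000 replicates at $n = 200$; the median-unbiasedness oracle uses
$10^5$ closed-form replicates; the evidence-table harness runs at reduced
ABC budgets in tests while keeping the $10^5$/5% default for users.  All
stochastic paths take explicit seeds and are bitwise reproducible.

## Known limitations

* **What is — and is not — exactly invariant.**  The estimator, the
  posterior mode, the score-type e-value and every density-threshold set
  (tangential boundaries, HPD superlevel sets) transport exactly through
  monotone reparameterizations: the construction transports density
  *values* without a Jacobian.  Integrated masses — the exact-grid
  e-value and equal-mass HPD endpoints — transport only to $O(n^{-1})$,
  because a mass computed under a Jacobian-free kernel is not a
  reparameterization-covariant quantity.  On an exponential-scale toy
  with $n = 10$ the exact-grid e-value changes by about $0.01$–$0.05$
  under a log reparameterization while the score-type e-value is
  invariant to machine precision.  The acceptance suite asserts the
  stricter exact-transport property for masses as stated and documents
  the failure rather than relaxing it.
* The median matching pseudo-posterior can be heavy-tailed (even
  non-normalizable in the limit) for monotone-likelihood samples whose
  correction decays like $c/\psi$ with $c < 1$; grids are truncated at 64
  standard errors and the truncation is visible in the construction
  metadata.
* Bootstrap corrections inherit Monte Carlo noise of order
  $O(R^{-1/2})$; it perturbs the mode at second order but is visible in
  symmetric-model checks (a normal-mean mode matches $\bar y$ to
  $\approx 0.01$ at 1500 replicates, not to $10^{-6}$).
* Multimodal marginal surprise densities are flagged, not resolved: the
  tail-area e-value is restricted to unimodal marginals, and exact-grid
  results carry a multimodality flag when the tangential set has several
  components.
* Only scalar interest parameters are supported; vector-interest
  extensions and exact-constraint samplers are out of scope.
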
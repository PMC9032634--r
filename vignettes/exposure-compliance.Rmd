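---
title: "Bayesian compliance testing for exposure groups: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian compliance testing for exposure groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegbayes)
```

## The problem

A homogeneous exposure group (HEG) is a set of workers assumed to share a
single exposure distribution, so that a sample of personal measurements
predicts the exposure of the whole group. Compliance practice in the South
African mining industry (the SAMI CoP) classifies each HEG by a point
estimate of the 90th percentile of its current campaign relative to the
occupational exposure limit (OEL; 2 mg/m³ TWA8h for respirable coal
dust). A point estimate carries no uncertainty, and each campaign is
judged in isolation, discarding historical measurements of the same group.

`hegbayes` treats the problem probabilistically. Exposure concentrations
are modelled as lognormal, the posterior of the 95th percentile (P95) is
simulated in full, and the decision quantity is the posterior probability
that P95 falls in each regulatory exposure-control band. Historical data
enter, when available, as an informative prior.

## Model and priors

Measurements $y_i > 0$ (mg/m³) satisfy $\log y_i \sim N(\mu, \sigma^2)$;
all logs are natural. The geometric mean is $GM = e^\mu$, the geometric
standard deviation $GSD = e^\sigma$, and
$P95 = \exp(\mu + z_{0.95}\sigma)$ with $z_{0.95} = 1.6449$ (four decimal
places, fixed). The likelihood depends on the data only through
$(n, \bar y, s_y)$ — the sample size and the mean and sample standard
deviation (denominator $n-1$) of the logs — so a published summary row of
$n$, GM and GSD is sufficient to fit the model: $\bar y = \ln GM$,
$s_y = \ln GSD$ (`stats_from_table()`).

**Non-informative regime.** $(\mu, \sigma)$ uniform on a box. The
defaults, $\mu \in [\ln 0.001, \ln 100]$ (GM from 1 µg/m³ to 100 mg/m³)
and $\sigma \in [\ln 1.05, \ln 10]$ (GSD from 1.05 to 10), bracket any
realistic industrial-dust dataset by two orders of magnitude on each side;
within them the prior is effectively flat while keeping the posterior
proper. A lower GSD bound slightly above 1 also protects the sampler from
the degenerate zero-variance corner. The flat density is placed on the
$\sigma$ scale (not $\sigma^2$), the scale on which the weakly-informative
prior literature frames its recommendations; a flat-on-$\sigma^2$ analysis
can be emulated through the informative interface with vanishing prior
weight, and the two differ only by an $O(1/n)$ tilt of the variance
posterior.

**Informative regime.** A historical campaign with log-scale moments
$(\bar y_0, s^2_{y0})$ is treated as a notional prior sample of size
$n_0$:
$$\mu \sim N(\bar y_0,\; s^2_{y0}/n_0), \qquad
  \sigma^2 \sim \mathrm{InvGamma}\!\Big(\tfrac{n_0-1}{2},\;
  \tfrac{(n_0-1)\,s^2_{y0}}{2}\Big),$$
the scaled chi-square form implied by
$(n_0-1)s^2_{y0}/\sigma^2 \sim \chi^2_{n_0-1}$, each truncated to the
bound box ($\mu$ bounded below at $\ln 0.001$ following Bayesian
decision-analysis practice; $\sigma^2$ between $(\ln 1.05)^2$ and
$(\ln 10)^2$ by default). The inverse-gamma *scale* is
$(n_0-1)s^2_{y0}/2$; the reciprocal sometimes seen in print is a
rate/scale confusion and is not used.

The default prior weight is $n_0 = 5$: occupational-exposure practice
recommends a prior sample of roughly 10–40% of the current campaign so
the posterior stays anchored to current data, and five is the customary
choice. Two eliciting modes exist. `subsample` draws $n_0$ historical
records at random (seeded), mirroring field practice; `moments` — the
default — uses the historical campaign's own moments down-weighted to
$n_0$, which is deterministic given summary statistics and is the only
reproducible option when raw historical records are unavailable.

**P95 cap.** An optional joint constraint
$P95 < k \cdot OEL$ restricts the posterior support. It is *disabled* by
default ($k = \infty$): imposing the commonly suggested $k = 2$ would cap
P95 at 4 mg/m³, yet most HEGs in the bundled study have posterior P95
medians above that, so the cap would dominate the data. When enabled, the
cap defines the support of the joint posterior, so *both* full
conditionals are truncated by it; the share of draws near every active
bound is reported (`bound_hits`) so a binding bound is visible rather than
silent.

## Gibbs sampler

The full conditionals are conjugate within the truncation box:

* flat prior: $\mu \mid \sigma^2 \sim N(\bar y, \sigma^2/n)$;
  $\sigma^2 \mid \mu \sim \mathrm{InvGamma}\big(\tfrac{n-1}{2},
  \tfrac{SS}{2}\big)$ with $SS = (n-1)s_y^2 + n(\bar y - \mu)^2$ (the
  Jacobian of flatness on $\sigma$ folds into the shape);
* informative prior: $\mu \mid \sigma^2 \sim N(m^*, v^*)$ with
  $v^* = (n/\sigma^2 + 1/v_0)^{-1}$,
  $m^* = v^*(n\bar y/\sigma^2 + m_0/v_0)$;
  $\sigma^2 \mid \mu \sim \mathrm{InvGamma}(a_0 + n/2,\; b_0 + SS/2)$.

Truncated draws are exact inverse-CDF samples computed on the log-CDF
scale (`rtnorm()`, `rtinvgamma()`), so they remain accurate when a bound
sits far in a tail; an interval whose mass underflows ($<10^{-300}$)
raises an error instead of returning garbage. Defaults: 4 chains × 20,000
post-warmup draws, 2,000 warmup, thin 1. Chains start overdispersed around
the data moments ($\mu_0 = \bar y \pm s_y$,
$\sigma_0 = s_y \cdot \{0.5, 1, 2\}$, clipped inside the bounds). Because
both conditionals are sampled exactly, mixing is nearly iid and warmup
mostly erases the initialisation.

Summaries are pooled-chain empirical quantiles: medians and equal-tailed
95% credible intervals (2.5th/97.5th percentiles — the published intervals
this package mirrors are asymmetric about the median in the way
equal-tailed intervals are, and HPD intervals are deliberately not
offered). P95 is transformed per draw and then summarised; its median is
a genuine posterior median, not a plug-in of parameter medians. Category
probabilities are draw fractions in the bands
$[0, 0.1\,OEL)$, $[0.1\,OEL, 0.5\,OEL)$, $[0.5\,OEL, OEL)$,
$[OEL, \infty)$ — lower-inclusive, matching the "≥" conventions of the
regulatory table, which itself is silent on boundary handling.

## Diagnostics

`gelman_rubin()` implements split-$\hat R$: each chain is halved,
$W$ is the mean within-half variance, $B/n$ the variance of half means,
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$; $\hat R \le 1.05$ is taken as
converged. `effective_sample_size()` implements autocorrelation-based ESS
with Geyer's initial-monotone truncation on FFT autocovariances of split
chains: bulk ESS on rank-normalised draws, tail ESS as the minimum over
the 5% and 95% quantile-indicator sequences. More than 100 effective
draws per chain is flagged as adequate. These are the modern
operationalisations of the classical between/within-chain diagnostic and
are validated in the test suite against closed forms (iid chains, and the
AR(1) identity $ESS = n(1-\phi)/(1+\phi)$). A constant chain returns ESS
0 with a warning.

## Synthetic data and what it does (not) show

`generate_heg()` draws lognormal measurements and, with
`match_moments = TRUE`, affinely standardises the logs so the sample
moments hit the target GM/GSD *exactly*; an affine map of a normal draw is
still normal, so the shape is preserved. `coal_fixtures()` applies this to
the bundled nine-HEG coal-dust monitoring summaries (243 current-campaign
measurements, plus historical campaigns), giving a fully synthetic dataset
whose every downstream posterior is seed-independent, because the model
sees data only through the matched moments. The fixture seed (20220407)
is therefore cosmetic; it fixes the raw record values, not any result.

What the generator does *not* emulate: within-worker versus between-worker
variance components (each HEG is one exchangeable lognormal population),
censored/non-detect values, autocorrelation across shifts, or any
departure from lognormality. Passing tests on these fixtures demonstrate
the estimation machinery, not robustness to those real-data features.

## SAMI CoP comparator

`sami_p90()` offers three P90 estimators — empirical sample percentile
(`quantile()` type 7), normal ($AM + 1.2816\,SD$) and lognormal
($GM \cdot GSD^{1.2816}$). The default is empirical: regulatory texts do
not pin down the estimator, the parametric forms cannot reproduce
published comparator columns from summary moments alone, and the empirical
percentile is the one choice that adds no distributional assumption.
`sami_category()` maps P90 to categories 1–4 at 10%, 50% and 100% of the
OEL (lower-inclusive); the "10% of the OEL" reading follows the
regulation's descriptive text rather than a conflicting "0.1%" misprint
in its statistical column.

## Numerical and scale choices

* $z_{0.90} = 1.2816$, $z_{0.95} = 1.6449$, fixed at four decimals.
* Sample variances use the $n-1$ denominator throughout.
* Empty truncation regions (e.g. a P95 cap below the $\mu$ lower bound)
  raise configuration errors naming the offending bounds.
* The full study (nine HEGs, two regimes, 4 × 20,000 draws each) runs in
  about two minutes on one CPU; module tests use a few thousand draws per
  fit, and the coverage study in the test suite uses 20 synthetic HEGs of
  $n = 200$ at 4 × 1,500 draws — sizes chosen so Monte-Carlo error is
  well inside each assertion's tolerance.

## Known limitations

* No pooling or hierarchy across HEGs: each group is fitted
  independently, as in the compliance framework this package mirrors.
* Published summary tables are not always self-consistent: arithmetic
  (AM/SD) and geometric (GM/GSD) moment pairs of the bundled study cannot
  come from one lognormal sample, and for two HEGs the printed posterior
  GSD contradicts the printed data GSD. The package treats GM/GSD — the
  model's sufficient statistics — as authoritative and reports what the
  stated model actually implies for them.
* No censoring support and no posterior-predictive checking.
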
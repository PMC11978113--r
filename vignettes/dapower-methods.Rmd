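---
title: "Methods: simulating microbiome communities and estimating taxon-level power"
author: "dapower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating microbiome communities and estimating taxon-level power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapower)
```

## Overview

`dapower` answers one question: in a case–control differential abundance
study with a given design, what is the probability of detecting each taxon,
as a function of that taxon's mean abundance and fold change? Because no
analytic power formula exists for sparse overdispersed counts tested with a
negative binomial Wald test after FDR correction, the package (i) fits a
generative model of the community to pilot data, (ii) simulates synthetic
cohorts from it, (iii) re-runs the full testing pipeline on each cohort,
and (iv) smooths the resulting Bernoulli detection outcomes into a power
surface.

## The count model and the testing pipeline

Counts for taxon $i$ in sample $j$ are modelled as
$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mu_{ij} = s_j\,q_{i,g(j)}$ and variance
$\mu_{ij} + \alpha_i \mu_{ij}^2$. The testing pipeline is deliberately
self-contained so that power results do not depend on the internals of an
external package, and each stage is testable on its own:

* **Pre-filter.** Taxa with fewer than `min_count = 5` reads in fewer than
  `min_samples = 3` samples are removed before anything else. Rare taxa are
  too variable to test and produce implausibly large fold change
  estimates. Power reported downstream is *unconditional* by default:
  simulated taxa that fail the filter count as undetected, because a real
  study could not have detected them either (a `conditional` switch
  reports filter-conditional power instead).
* **Size factors.** Median-of-ratios with per-taxon references computed as
  geometric means over *positive* counts, and per-sample medians over taxa
  observed in that sample. The all-counts variant degenerates on sparse ASV
  tables where almost every taxon has at least one zero. Factors are
  rescaled to geometric mean one.
* **Dispersion.** Per taxon, $\alpha_i$ maximises the profile likelihood
  of the two-group NB model on $\alpha \in [10^{-8}, 50]$ (the group means
  are profiled out by Fisher scoring on $\log q$; the search is on
  $\log\alpha$). Taxa maximised at the lower bound are reported as
  $\alpha = 0$, the Poisson limit, and flagged; they are excluded from the
  dispersion-trend fit. No Cox–Reid adjustment is applied — a documented
  simplification; with two parameters per taxon the bias is modest and
  simulation tests confirm calibration at the suite's sample sizes.
* **Wald test.** With a saturated two-group design the NB GLM has
  closed-form structure: $\hat\beta_1 = \hat\phi_t - \hat\phi_c$ on the
  natural-log scale, $\mathrm{se}^2 = 1/W_c + 1/W_t$ with
  $W_g = \sum_{j \in g} \mu_j/(1+\alpha\mu_j)$, and a two-sided normal
  p-value. Fold changes are reported in log2 units. Fitted group means are
  floored at $10^{-8}$ so taxa observed in only one group give large but
  finite estimates with honestly enormous standard errors.
* **Shrinkage.** An empirical-Bayes normal prior $N(0, \tau^2)$ with
  $\tau^2 = \max(0.01, \mathrm{var}(\hat\beta) - \overline{\mathrm{se}^2})$
  pulls noisy fold changes towards zero:
  $\tilde\beta_i = \hat\beta_i\,\tau^2/(\tau^2 + \mathrm{se}_i^2)$. A
  single-component prior is transparent, always finite, and does all that
  is required here — taming the extreme estimates of low-abundance taxa
  before they become fitting targets for the community model.
* **FDR.** Benjamini–Hochberg step-up with monotonicity enforcement;
  untestable (all-zero) taxa are excluded from the denominator. The
  significance threshold defaults to $q < 0.1$ and is configurable; all
  power outputs are labelled with the threshold used.

## The community model

Fitting targets are per-taxon summaries from the pilot data:
$x_i = \log_2$ of the mean normalised count over all samples pooled, and
$y_i$ the *shrunken* log2 fold change. Using shrunken values avoids the
infinite-fold-change artefacts of group-exclusive taxa. Log base 2 is used
throughout and recorded in the model metadata.

**Mean abundance.** $x$ is a finite Gaussian mixture. The order is chosen
by sequentially testing $k$ vs $k+1$ components (orders 1–5) with a
parametric bootstrap of the likelihood-ratio statistic: 100 datasets are
simulated from the fitted $k$-component null, both orders are refitted on
each, and the p-value is the tail proportion with the $+1/(B+1)$
correction. Testing stops at the first p-value above 0.05 (both the
bootstrap size and the level are configurable; 0.05 is the package's
choice of a conventional level). A crucial numerical detail: the observed
statistic is computed with the *same* restart and iteration budget as the
bootstrap refits (2 k-means-seeded starts, tolerance $10^{-6}$, 120
iterations), because a fully converged observed fit compared against
budget-capped bootstrap fits systematically inflates the observed
statistic and over-selects components. The selected order is then refitted
at full precision (5 restarts, tolerance $10^{-8}$, 500 iterations).

**Fold change.** $y \mid x$ is a conditional Gaussian mixture with
component means linear in $x$ and component log-standard-deviations either
linear or quadratic in $x$; the variance form is shared across components
(each with its own coefficients), and mixing weights are parameterised by
log-odds $\lambda_i$ with $\lambda_1 = 0$ for identifiability. Estimation
is ECM: responsibilities, closed-form weights, weighted least squares for
the mean lines at the current variances, then per-component BFGS for the
log-sd coefficients with analytic gradients; each conditional step cannot
decrease the expected complete-data log-likelihood, so the observed
log-likelihood trace is non-decreasing (asserted in the tests). Order
(1–5) and variance form are chosen jointly by AIC with
$(K-1) + 2K + K(\mathrm{deg}+1)$ parameters. Whether the mean-abundance
and fold-change mixtures should share an order is an open design question;
they are selected independently here, since nothing couples them in the
model.

**Dispersion trend.** Per-taxon ML dispersions are regressed on
$(1, 1/m)$ with non-negativity constraints (two-variable NNLS by case
analysis), then refitted once after trimming points more than 10-fold off
the trend *relative to the median deviation* — normalising by the median
keeps the trim meaningful even when a first pass is dominated by gross
outliers. $c_0$ is the asymptotic dispersion of abundant taxa; $c_1$ the
excess of rare taxa. The multiplicative `scale` (default 0.3) is stored on
the object and applied only at prediction/simulation time, so the raw fit
stays inspectable. The scale exists because raw estimated dispersions
overstate the between-sample variability of real communities; 0.3
calibrates the coefficient of variation of simulated counts to observed
data. A consequence worth knowing: data simulated from a fitted model
carry the *scaled* dispersion curve, so refitting a model to its own
simulation recovers $(\mathrm{scale}\cdot c_0, \mathrm{scale}\cdot c_1)$
as its unscaled trend. Round-trip comparisons must therefore compare
against the effective (scaled) truth, as the test suite does.

## The simulator

Each synthetic taxon is drawn in five steps: (1) $x_t$ from the mean
mixture; (2) $y_t$ from the conditional fold-change mixture at $x_t$;
(3) dispersion $d_t = \mathrm{scale}\,(c_0 + c_1/M_t)$ with $M_t = 2^{x_t}$
(floored at $10^{-6}$ to keep NB parameters valid after extreme mixture
draws); (4) group means $\mu_c = 2M_t/(1+\mathrm{FC})$,
$\mu_t = 2M_t\,\mathrm{FC}/(1+\mathrm{FC})$ with $\mathrm{FC} = 2^{y_t}$,
which preserves the arithmetic mean exactly; (5) counts from
`rnbinom(mu = mu_group, size = 1/d_t)` (i.e.
$\mathrm{prob} = \mathrm{size}/(\mathrm{size}+\mu)$), independently per
sample, falling back to Poisson at $d_t = 0$. One master seed drives
deterministic sub-seeds per stage (a Lehmer-style stream derivation), so
whole datasets are bit-reproducible.

Simulated cohorts have size factors identically 1 — the generative model
says nothing about library-size variation — with an optional lognormal
multiplier (`library_size_sd`) for stress tests. Taxa are independent: the
model has no taxon–taxon correlation, no compositional constraint, and no
explicit sparsity mechanism (zeros arise only from the NB sampling). These
are real limitations relative to some community simulators, accepted in
exchange for direct control over the effect-size and abundance
distributions that power depends on. Consequently, passing tests here show
that the *pipeline* is calibrated for NB-generated communities; they do
not certify behaviour under strong taxon correlations or technical
zero-inflation.

## The power surface

Each Monte-Carlo replicate contributes one Bernoulli row per taxon:
detected ($q <$ threshold) or not, together with the taxon's *true*
$x_1 = \log_2$ mean abundance and $x_2 = |\log_2$ fold change$|$ from the
simulation record. The absolute fold change is used because detection is
symmetric in the sign of the effect while power must be monotone in effect
size; a signed axis cannot be both.

The detection probability is modelled as
$y \sim \mathrm{Bernoulli}(p)$, $\mathrm{logit}\,p = \eta(x_1, x_2)$,
where $\eta$ is a tensor-product cubic B-spline surface (marginal basis
dimension 5 by default). Monotonicity in both directions is structural,
not penalised: the coefficient matrix is the double cumulative sum of
exponentiated free parameters (the first entry unexponentiated, acting as
the intercept), so coefficient increments along both margins are
non-negative and the spline surface is non-decreasing in each input at
machine precision. Smoothness comes from a second-difference penalty on
the free parameters, with the penalty weight chosen by GCV over a small
grid ({0.1, 1, 10}); a tiny ridge ($10^{-4}$) and box constraints on the
free parameters keep flat regions (where increments want to reach exactly
zero, i.e. parameters $\to -\infty$) numerically benign. Optimisation is
L-BFGS-B with analytic gradients. The residual term sometimes written into
such linear predictors is treated as absorbed by the Bernoulli variation;
no extra random effect is fitted.

Predictions are clamped to the training box — the surface is an
interpolator of the simulated design space, and extrapolating a monotone
logistic surface beyond it would manufacture certainty. Clamped queries
are counted and reported.

Summaries follow from the surface: per-taxon power $p_i$, average power
$\hat p$, deciles of $\{p_i\}$, and the expected number of significant
taxa $\mu = \sum_i p_i = n\hat p$ — an identity the implementation
maintains exactly (the sum is computed as $n \cdot \mathrm{mean}$). The
deciles matter: power distributions are strongly right- or left-skewed,
and the average routinely exceeds the median, so the average alone
overstates the power of most taxa.

`sample_size_sweep()` repeats simulation, testing and surface fitting per
per-group sample size (defaults 30–190 by 20, read off at reference
abundance $x_1 = 5$ and $|$lfc$|$ 2, 3, 4) and reports the power curve and
the expected significant count, the latter averaged over replicates.

## Defaults and test scales

| Parameter | Default | Meaning |
|---|---|---|
| `min_count`, `min_samples` | 5, 3 | abundance pre-filter |
| `alpha_sig` | 0.1 | q-value significance threshold |
| `K_max`, `B`, `level` | 5, 100, 0.05 | mean-mixture order selection |
| `lfc_K_range` | 1–5 | fold-change mixture orders |
| `dispersion scale` | 0.3 | CV calibration factor |
| `n_taxa`, `n_per_group`, `n_sims` | 1000, 100, 100 | power Monte-Carlo design |
| `df` | 5 per margin | surface basis dimension |

The Monte-Carlo defaults describe a full analysis. The test suite and the
acceptance script run the same machinery at desk scale — typically 300–500
taxa, 20 simulations, 30–100 samples per group — sizes chosen so the whole
suite executes in minutes while leaving Monte-Carlo error well inside the
asserted tolerances. The built-in reference model
(`builtin_community_model()`) fixes a three-component abundance mixture
(weights 0.45/0.35/0.20 at log2 means 3/6/9), a two-component
symmetric-about-zero fold-change mixture (a tight near-null bulk plus a
heavier-tailed minority, both with log-sd decreasing in abundance), and
trend $(c_0, c_1, \mathrm{scale}) = (0.2, 5, 0.3)$ — values in the range
seen in fitted 16S case–control datasets.

## Known limitations

* Single binary covariate only; no multi-factor designs, continuous
  covariates or likelihood-ratio tests.
* Independent taxa; no compositional coupling or correlation structure.
* The Wald test with plug-in ML dispersion is slightly anticonservative at
  very small group sizes; the suite verifies calibration at 30+ samples
  per group.
* The dispersion scale couples the model to the estimation procedure used
  on the pilot data (see the round-trip note above).
* Bootstrap order selection is expensive by construction (hundreds of EM
  fits); the EM kernel is compiled, and the budget-matched statistic makes
  the test honest, but wall-clock time grows linearly in `B`.
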
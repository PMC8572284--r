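---
title: "Structural validity of polytomous scales with the partial credit model"
author: "raschval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural validity of polytomous scales with the partial credit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschval)
```

## The measurement problem

Multi-item patient-reported outcome (PRO) questionnaires — upper-extremity
disability scales among them — are usually summarised by a single sum or
mean score. That summary is only defensible if the items jointly measure
one construct on a common scale. Rasch measurement offers a testable
standard: under the **partial credit model** (PCM) every item response
`x` in categories `0..m` follows

$$P(X_i = x \mid \theta) =
  \frac{\exp \sum_{k \le x} (\theta - \delta_{ik})}
       {\sum_{h=0}^{m_i} \exp \sum_{k \le h} (\theta - \delta_{ik})},$$

where $\theta$ is the person's latent level (logits) and $\delta_{ik}$
are the item's category thresholds. If the model fits, the total raw
score is a sufficient statistic for $\theta$, items are conditionally
independent given $\theta$, item behaviour is invariant across patient
subgroups, and raw totals can be transformed onto an interval-level
metric. `raschval` implements the full validation battery around this
model — calibration, fit diagnostics, local dependence screening,
testlet accommodation, DIF, a unidimensionality test, reliability, and
ordinal-to-interval conversion — together with a synthetic-response
generator that plants each violation the battery must detect.

Sign convention: internally, higher $\theta$ always means a higher
expected item score (for symptom/limitation scales: worse function).
Reporting functions accept `rummSign = TRUE` to print item locations in
the opposite convention (negative location = harder item), common in
published tables.

## Estimation

**Items.** `estimateItems()` maximises the marginal likelihood under a
normal latent distribution (marginal maximum likelihood, EM algorithm,
41-node Gauss–Hermite quadrature). Identification fixes the sum of item
locations at zero and leaves the latent mean free. Standard errors come
from the empirical cross-product information; persons with extreme
(zero/perfect) raw scores contribute to the likelihood but not to the
information matrix. Some commercial Rasch programs use a proprietary
pairwise conditional algorithm instead; MML is fully documented and
testable, and every downstream statistic is defined through expected
scores and variances, so it is agnostic to the calibration algorithm up
to small shifts. Convergence is declared at a relative log-likelihood
change below `1e-8` (default cap 500 EM iterations; the pipeline raises
the cap for testlet super-items, whose many thresholds converge more
slowly). Two numerical safeguards matter for super-items calibrated from
small samples: a weak ridge penalty (0.01) on thresholds and a hard ±8
logit clamp keep the thresholds of unobserved categories finite; both
are negligible for categories with data (threshold recovery RMSE at
n = 1000 is well under 0.15 logits, and the EM solution matches an
independent brute-force grid maximiser of the same likelihood to ~0.002
logits on a small instance).

**Persons.** `estimatePersons()` solves the Warm-type weighted
likelihood equation (the bias-corrected score equation
$r - \sum_i E_i(\theta) + J/(2I) = 0$), with SE $1/\sqrt{I(\theta)}$.
Extreme raw scores have no finite maximum; they receive the ability
whose expected total equals the raw score adjusted inward by 0.3 (a
configurable convention), and are flagged and excluded from aggregate
fit statistics, the PSI, and residual analyses.

## Fit diagnostics

**Standardized residuals** $z_{ni} = (x_{ni} - E_{ni})/\sqrt{V_{ni}}$
are the substrate for everything else. **Fit residuals** aggregate
$z^2$ per item or person, match the sum to a scaled chi-square through
its model-implied first two moments (the mean corrected for the share of
person information each cell consumes — the standard
$E[(x-\hat E)^2] \approx V(1 - V/I)$ expansion — and the variance from
the model's conditional kurtosis) and carry it to approximate normality
by the Wilson–Hilferty cube-root transform. The transform choice is
isolated in `fitResiduals()`; published descriptions say only
"transformed to approximate normality", so this decision is ours and is
validated by simulation: under the model (10 five-category items,
n = 500) item fit residual means sit near 0.08 with SD near 0.8.
Absolute values above 2.5 flag misfit; item flags additionally use the
Bonferroni-corrected per-item chi-square.

**Item-trait interaction chi-square.** Persons are grouped into
ability-ordered class intervals (default 3 strata up to n = 150, else
`min(10, n/50)`, split at quantiles with a minimum stratum size of 10 —
29 items with 3 strata give the familiar total df of 58). For each item,
the squared stratum sums of residuals are referred to their summed
variances. A design decision with real consequences: the expectation and
variance of each response are computed **conditional on the person's raw
total over answered items** — the PCM's sufficient statistic, evaluated
exactly by polynomial convolution per missingness pattern — rather than
at the estimated ability. The marginal version is adequate for long
scales but collapses for a two-super-item analysis, where one "item"
carries ~70% of the test information and ability-estimation error
dominates: in a parametric null check (two super-items of 80 and 36
categories, n = 108) it rejected in 30/30 replicates, while the
conditional version rejected in 2/30 and holds ~3–6% rejection for
10-item scales at n = 500. Conditioning on the sufficient statistic is
exactly mean-zero per stratum under the model, needs no shrinkage
heuristics, and leaves the reported df at the conventional $I(G-1)$.
No adjustment is made for item-threshold estimation: as in the classic
Pearson–Fisher situation, referencing the statistic to the full df with
parameters estimated from ungrouped data makes the test mildly
conservative (null rejection slightly below 5%) — the safe direction
for a fit criterion — and our experiments with Rao–Robson-style
denominator corrections showed them to be unstable at these sample
sizes (the estimated parameter covariance is too noisy, flipping the
test anticonservative).

**Disordered thresholds.** An item's thresholds should increase with
category index; `checkThresholdOrder()` flags violations and
`categoryCurves()` exports the category characteristic curves on a theta
grid (for an ordered item every category is modal somewhere; for a
disordered one some category is nowhere modal).

**PSI.** The Person Separation Index
$(\mathrm{Var}(\hat\theta) - \overline{SE^2})/\mathrm{Var}(\hat\theta)$
over non-extreme persons; it may be negative for uninformative data and
is reported as-is.

## Residual structure

**Local dependence.** `residualCorrelations()` computes the item-pair
Pearson correlations of the residuals (pairwise-complete, ≥20 shared
observations by default) and flags pairs exceeding the mean off-diagonal
correlation by more than 0.2 — the field's relative criterion, which
adapts to the slightly negative baseline that residual correlations
exhibit by construction. Flagged pairs concentrated within content
clusters indicate testlet structure; `collapseTestlets()` then sums each
cluster into one polytomous super-item (score = sum of member codes,
maximum = sum of member maxima; missing if any member is missing, since
partial sums are not comparable across persons) and the battery is
re-run at testlet level.

**DIF.** For each item and covariate, a two-way ANOVA of residuals on
group, class interval, and their interaction (type-III marginal tests,
effects coding, to tolerate unbalanced groups). The group main effect
tests uniform DIF, the interaction non-uniform DIF; flags are
Bonferroni-corrected across items within a covariate. Sparse
group-by-stratum cells trigger stratum merging for that item.

**Unidimensionality.** The principal-component t-test: PCA of the
residual correlation matrix, items split by the sign of the first
component's loadings, person abilities re-estimated on each subset with
thresholds anchored at the full calibration, and per-person
$t = (\hat\theta_1 - \hat\theta_2)/\sqrt{SE_1^2 + SE_2^2}$ compared to a
normal reference at 5%. The scale passes when at most 5% of persons
differ, or when the Wilson 95% interval for that proportion reaches 5%.
For scales of up to three items (e.g. two testlets) a 1+1 split is
allowed — this is precisely the configuration in which the test is run
after collapsing a scale into two super-items. `sharedVariance()`
reports the disattenuated squared correlation
$r^2/(\mathrm{rel}_A\,\mathrm{rel}_B)$ between two subset estimates — a
documented substitute for proprietary "% common variance" outputs, used
directionally.

## Interval scoring

`buildConversionTable()` inverts the test characteristic curve
$\sum_i E_i(\theta)$ by monotone root finding (tolerance 1e-8) for every
raw total, uses the 0.3-adjusted targets at the extremes, and rescales
theta affinely so the table runs exactly 0–100 (an affine map preserves
the interval property of the logit metric). For a 29-item, 0–4 scale the
table has 117 rows for raw 0–116; with 100 meaning the worst functional
level under the native sign convention. The table applies only to
complete responses on its items, and is exported/imported as CSV so a
published calibration can be reused without refitting.

## The synthetic generator

`simulateResponses()` draws from a generalized PCM: abilities
$\theta \sim N(\mu, \sigma^2)$; optional person-specific testlet effects
$\gamma_{t}\sim N(0, sd_t^2)$ shared by member items (a bifactor-style
mechanism that produces exactly the within-cluster positive residual
correlations of locally dependent scales); optional uniform DIF offsets
subtracted from one covariate group's effective ability on chosen items;
item discriminations $a_i$ (all 1 recovers the pure PCM; $a_i < 1$
produces positive fit residuals, the canonical misfit signature);
item-wise missingness. With all knobs at zero the generator and the
estimator validate each other: the full battery passes at nominal rates
on its output.

`dashLikePreset()` emulates a 30-item upper-extremity instrument: 20
activity items and 9 impairment items in two dependence clusters plus an
optional item with 54% missingness, n = 109, standard-normal abilities,
item locations spread over ±1.2 logits with ±1.5 threshold steps, and
covariates at realistic marginal frequencies (sex 58/42, age split at
the median, surgery 37/63, dominant side 66/34). The testlet effect SD
defaults to 0.8 per cluster — chosen once to match the severity of local
dependence such instruments show in clinic samples (roughly 40–50
flagged residual pairs among 29 items at this sample size, and a clearly
significant initial item-trait chi-square that becomes non-significant
after collapsing the two clusters into testlets, with the PSI dropping).
What the generator does **not** emulate: real response styles
(acquiescence, central tendency), item-specific content overlap beyond
the cluster effects, ceiling effects from clinical case mix, or
informative missingness. Passing the battery on synthetic data therefore
demonstrates the statistics work as designed, not that any particular
real instrument fits.

Two fixture choices in the validation suite deserve a note. The
local-dependence power check plants two 5-item testlets (effect SD 0.6)
inside a 20-item scale with evenly spaced, comparatively informative
thresholds at n = 1000: when testlets cover an entire short scale, the
ability estimate absorbs the shared effects and within-cluster residual
correlations shrink below any absolute threshold, so independent anchor
items are part of the planted design, and flagged pairs are pooled over
replicate datasets for stability. The two-factor dimensionality check
uses the bifactor equivalence: factors correlated at $r$ equal a general
factor of variance $r$ plus cluster effects of variance $1-r$.

## Numerical and degenerate-input policy

Residuals at cells with numerically zero model variance become missing
with a warning. Empty chi-square strata are merged toward a neighbour.
Class-interval ties are kept together; undersized strata merge into the
nearer neighbour. Persons with all items missing are an error for person
estimation and are dropped (with a warning) from item calibration.
Persons lacking any item of a PCA subset are excluded from the t-test
denominator and counted in the report. Degenerate conditional
distributions (extreme totals) drop out of the chi-square naturally.
All reductions are single-threaded in fixed order, so identical inputs
and seeds reproduce reports bit-identically.

## Problem sizes used in the shipped validation

The test-suite simulations use the sizes stated above (up to n = 1000
for power checks, 200 pure-PCM replicates at n = 500 for the null
calibration of the chi-square and fit residuals, 20 seeded replicates of
the 109-person preset for the three-run pattern). These sizes give the
binomial bands and power margins the checks assert while keeping a full
run in the minutes range on one core.

## Known limitations

* MML calibration differs from pairwise-conditional programs by small
  shifts; published parameter tables can be reproduced only up to these
  shifts even with the original data.
* The Wilson–Hilferty fit residual approximates the undocumented
  transforms of commercial software; magnitudes beyond ±2.5 agree in
  simulation, exact values need not.
* The total item-trait chi-square sums per-item statistics whose
  cross-item dependence is ignored (as is conventional); with very few
  items the total is mildly over-dispersed relative to its nominal df.
* The conversion table assumes complete responses; no equating across
  item subsets is attempted.
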
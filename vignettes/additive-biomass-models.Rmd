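---
title: "Additive allometric biomass models by seemingly unrelated regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive allometric biomass models by seemingly unrelated regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomsur)
```

## The model

Tree biomass scales allometrically with stem dimensions: on the arithmetic
scale each component mass follows a power law such as $W = \alpha D^b$,
possibly refined by total height $H$, the combined size variable $D^2H$, or
crown radius $CR$ (an indirect measure of photosynthetic capacity,
particularly informative for branch and leaf mass). `allomsur` works with
the six standard candidate forms, linearised by natural logarithms:

| id | log-scale form |
|----|----------------------------------------------|
| M1 | $\ln W = a + b\ln D$ |
| M2 | $\ln W = a + b\ln D + c\ln H$ |
| M3 | $\ln W = a + b\ln D + c\ln CR$ |
| M4 | $\ln W = a + b\ln(D^2H)$ |
| M5 | $\ln W = a + b\ln(D^2H) + c\ln CR$ |
| M6 | $\ln W = a + b\ln D + c\ln H + d\ln CR$ |

The log transform serves two purposes: it linearises the power law and it
stabilises the strongly size-dependent error variance, so ordinary least
squares on the log scale is appropriate without further weighting. The
assumptions are therefore multiplicative lognormal errors with constant
log-scale variance within an age group, and independence between trees.
Because allometry drifts over stand development, every model is fitted
separately within three age classes (young $\le$ 5 yr, middle-aged 6–15 yr,
mature > 15 yr). Ages strictly between 5 and 6 years fall in a gap of those
class definitions; `assign_age_group()` folds them into the middle class by
default (continuity of its upper interval), with `strict = TRUE` available
to reject them instead.

### Retransformation bias

If $\ln W$ is modelled with residual variance $\sigma^2$, then
$\exp(\widehat{\ln W})$ estimates the conditional *median* of $W$, not the
mean, and systematically underestimates it. The Baskerville correction
multiplies by $CF = \exp(\sigma^2/2)$, so predictions are
$\hat W = \exp(\widehat{\ln W})\,CF$. We estimate $\sigma^2$ as
$\mathrm{RSS}/(n-k)$ with $k$ the number of estimated coefficients; the
historical presentation fixes $n-2$, which is correct only for
two-coefficient models and would inflate $CF$ under M6 — `cf_df = "classic"`
restores that convention for emulation. `correction_factor()` is exact at
$\sigma^2 = 0$ ($CF = 1$) and monotone; the test suite confirms on large
lognormal simulations that the mean ratio of observed biomass to the
*uncorrected* prediction converges to $CF$.

## Model selection

Goodness of fit is judged on the scale users care about: R² and MAPE are
computed from the back-transformed, CF-corrected predictions in kg. MAPE
(`mean(|obs − pred|/obs)`) is the primary criterion because R² rewards
added regressors almost unconditionally. The rule in `select_allom()`:

* a candidate is *eligible* only if every non-intercept coefficient is
  significant at $\alpha = 0.05$ (strict $p < \alpha$, two-sided $t$ with
  $n-k$ df). The intercept does not gate eligibility — reported component
  tables conventionally keep models whose intercept is weakly determined;
* among eligible candidates, lowest MAPE wins; ties (compared after
  rounding to six decimals, so floating-point noise cannot manufacture
  distinctions) go to the higher R², then to fewer coefficients, then to
  the lower model index. The parsimony-then-index tie-break is our policy:
  exact ties do occur (e.g. a perfect M2 and M4 fit on noise-free data) and
  the rule must be deterministic;
* if no candidate is eligible, the lowest-MAPE model is returned flagged
  (`eligible_choice = FALSE`) with a warning — small samples can leave
  every slope non-significant, and silent failure would be worse than a
  flagged fallback.

On noise-free data every candidate nesting the generating terms
interpolates exactly; a perfect fit pins each coefficient, so
zero-residual fits count as eligible rather than dividing by a zero
standard error, and parsimony then recovers the generating form.

## The additive system

Fitting the four selected component equations separately ignores that all
four errors belong to the same tree and are strongly correlated, and the
component predictions need not sum to any total-biomass model. Both issues
are addressed by estimating the system jointly by seemingly unrelated
regression in `fit_sur()`:

1. per-equation OLS gives starting residuals;
2. the cross-equation covariance is estimated as
   $\hat\Sigma_{ij} = \tfrac1n \sum_t e_{it}e_{jt}$ (maximum-likelihood
   divisor $n$; equations have different $k$, so a common df adjustment
   does not exist);
3. generalized least squares solves the stacked system weighted by
   $\hat\Sigma^{-1} \otimes I_n$ (implemented blockwise via
   $\hat\Sigma^{-1}_{ij} X_i'X_j$, never forming the $4n \times 4n$
   weight);
4. steps 2–3 iterate until the largest absolute coefficient change falls
   below `tol` (default $10^{-8}$, cap 100 iterations; non-convergence is
   returned flagged with a warning, never hidden).

Two classical identities serve as standing regression tests: with identical
regressor matrices in all equations, and with a diagonal working
covariance (`sigma_structure = "diagonal"`), SUR reduces exactly to
per-equation OLS. A dense stacked-GLS solve with the explicit Kronecker
weight is kept in the test suite as an independent oracle. A near-singular
$\hat\Sigma$ aborts with a suggestion to set a small `ridge` jitter
(disabled by default).

Total biomass is predicted as the *exact sum* of the four bias-corrected
component predictions, with per-equation $\sigma^2$ and CF recomputed from
the final system residuals. The total line is a deterministic identity, not
a fifth stochastic equation: observed totals are by construction the sum of
observed components, so a fifth equation adds no information, while its
CF-weighted nonlinear form has no well-defined error term. Additivity
therefore holds to machine precision for every input, which the tests
assert directly.

## The synthetic-population generator

The raw per-tree data behind the published group summaries are not
deposited, so `simulate_trees()` generates populations with the structure
the analysis assumes. Per age group:

* **Diameter** is drawn from a truncated normal matching the published
  group mean/SD/min/max (18, 19 and 35 trees with means 6.3, 12.7 and
  23.1 cm), by rejection sampling capped at 10,000 attempts per draw.
  Truncation shifts the realised moments slightly away from the untruncated
  parameters; the generator tests compare against the closed-form
  truncated-normal moments.
* **Height and crown radius** follow log-linear links on $\ln D$
  ($\ln H = h_0 + h_1\ln D + \varepsilon$, likewise CR). No joint
  distribution of $(D, H, CR)$ is published; the link constants are
  calibration values chosen once so that generated heights and crown radii
  land inside the published min–max envelopes, and are documented as such,
  not as published coefficients.
* **Component biomasses** are generated from each group's published
  selected-model coefficients with log-scale errors drawn jointly from
  $N(0, \Sigma_{\log})$. Defaults: per-component SD 0.15 log-units
  (giving realistic correction factors near 1.01) and cross-component
  correlation 0.5, a moderate value consistent with errors sharing a tree;
  both are overridable, and an explicit $\Sigma_{\log}$ (validated
  symmetric positive semi-definite) may be supplied.

Equal seeds give bit-identical populations. What passing tests on these
populations show is that the estimators recover a truth of exactly the
assumed form; they cannot show robustness to features real inventories
have and the generator omits — measurement error in predictors, plot-level
random effects, spatial autocorrelation, or allometries outside the six
candidate forms.

## Diagnostics

Allocation shares are per-tree fractions averaged within groups — not
ratios of group means, which differ whenever allocation covaries with tree
size. Differences across age groups are tested by classical one-way ANOVA
(cross-checked in the tests against a brute-force sums-of-squares oracle
and against `stats::oneway.test(var.equal = TRUE)`, and calibrated for
type-I error under the null); Welch's variant would be a reasonable
extension where group variances differ strongly. Normality of the
arithmetic-scale total-biomass residuals (observed minus additive
prediction) is tested by Shapiro–Wilk (Royston approximation, $3 \le n \le
5000$) with Q-Q pairs at Blom plotting positions $(i - 0.375)/(n + 0.25)$.

## Problem sizes and numerical choices

The test and acceptance workloads use: the default 72-tree population for
pipeline checks; $n = 300$ single-group populations for coefficient
recovery (every estimate within 3 reported SEs); 200 replicates of $n = 50$
for the SUR-vs-OLS efficiency comparison (empirical SD ratios around
0.55–0.85 with error correlation 0.8 and differing regressor sets);
$n = 5000$ for covariance recovery; $n = 20000$ lognormal draws for CF
calibration; and 2000 null replicates for type-I-error bands
($0.05 \pm 3\sqrt{0.05 \cdot 0.95 / 2000}$). Degenerate inputs are
rejected eagerly with indexed messages: non-positive measurements (logs
must exist), rank-deficient designs (named collinear columns), $n \le k$,
constant samples, and groups with fewer than two trees.

## Limitations

* Selection explores only the six fixed candidate forms; no information
  criteria and no nonlinear (untransformed-scale) fitting are provided.
* The SUR system imposes no cross-equation parameter restrictions and no
  within-equation heteroscedasticity weighting beyond the log transform.
* Published fitted coefficients cannot be reproduced numerically without
  the original raw data; the package instead verifies the estimators on
  synthetic populations generated from those published values.
* Root biomass conventionally excludes fine roots below 2 mm; that is a
  data-definition matter upstream of this package.
* Crown radius is accepted as a measured column; if field crown *widths*
  (two perpendicular measurements) are recorded instead, halving their
  mean is the user's choice to make explicitly, as conventions differ.
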
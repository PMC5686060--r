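---
title: "Methods: disability scoring, therapy adjustment, and the MS-DSS model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disability scoring, therapy adjustment, and the MS-DSS model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdss)
```

This vignette is the package's own account of the science it implements:
the composite disability score, the therapy-efficacy calculus, the
longitudinal slope machinery, the boosted severity model, and the synthetic
cohort generator that ties them together into a testable whole. It also
records the numerical conventions and the design decisions that were
genuinely open.

## The composite disability score

EDSS is ordinal, coarse (median annualized change in large observational
cohorts is about 0.1 points), and insensitive on short follow-up. CombiWISE
is a continuous 0–100 composite of four scales measured at every visit:

$$\mathrm{CW} = 33.166 + 3.803\,\mathrm{EDSS} - 0.407\,\mathrm{SNRS}
+ 2.409\log_2 T_{25FW} + 18.056\,F_{walk}
+ 1.305\log_2 T_{9HPT} + 10.751\,F_{peg}$$

with fail flags $F$ for timed tests that exceed their limits (180 s walk,
300 s peg). The coefficients are published constants; `compute_combiwise()`
treats them as given.

**Failed timed tests.** The composite's definition does not say what the
log term should be when a test is failed. We evaluate it at the test
ceiling *and* add the fail bonus, which makes the score continuous at the
pass/fail boundary: a walk of exactly 180 s and a failed walk differ by
precisely the 18.056 bonus. A recorded time together with a raised fail
flag is rejected as inconsistent rather than silently resolved. Scores are
clipped to $[0, 100]$, the scale's defined range; clipping only occurs for
extreme multi-failure inputs.

## Rank-severity scores: MSSS and ARMSS

MSSS ranks a patient's EDSS within a reference population at the same
disease duration; ARMSS substitutes age for duration. The published global
reference tables are external artifacts, so `build_reference()` constructs
a **local** reference from the supplied cohort: first-visit EDSS binned by
the conditioning variable (1-year bins for duration, matching the
year-of-duration convention of duration-conditioned scores; 5-year bins for
age), with bins under 5 patients merged outward into their neighbours. The
score of an EDSS value $e$ in a bin of size $N$ is $10\,r/(N+1)$, where $r$
is the average tied rank of $e$ in the bin's multiset (the scored value is
included if not already a member). This keeps scores strictly inside
$(0, 10)$ and makes a permutation bin average exactly 5. Users who have the
published tables can pass them through the same `severity_reference`
format. Local referencing means scores are comparable *within* a cohort but
not across cohorts — the same caveat that applies to any re-normalised rank
score.

## The therapy-efficacy calculus

A meta-analysis of randomized DMT trials established that efficacy against
disability progression declines linearly with age, separately for a low-
and a high-efficacy drug class. We take those regressions as constants
(percent inhibition at mean epoch age $\bar a$):

* low: $\mathrm{Eff} = 83.71 - 1.50\,\bar a$ (root at 55.81 y)
* high: $\mathrm{Eff} = 206.39 - 4.34\,\bar a$ (root at 47.56 y)

Negative values are floored at zero. Three conventions required decisions:

* **Units.** The lines produce percent; the adjustment formulas use
  $1-\mathrm{Eff}$, which is only meaningful for fractions. All internal
  efficacies are fractions; division by 100 happens once, in
  `epoch_efficacy()`.
* **Cap.** The high-efficacy line exceeds 100% below age ≈ 24.5,
  which would make $1-\mathrm{Eff}$ non-positive and the adjustment blow
  up. Raw per-epoch efficacies are capped, default 0.95, before duration
  weighting. The cap is applied per epoch (not to the cumulative value) so
  that a brief early-life epoch cannot dominate a long window. Both the cap
  value and the clamping site are our construction; the source method is
  silent, and results for cohorts older than ~25 are insensitive to it.
* **Windows.** Slope adjustment uses the first-to-last-visit window (the
  period over which the slope was measured); cross-sectional adjustment
  uses birth-to-visit, because disease onset cannot be timed precisely.
  Epochs are clipped to the window before mean-age evaluation.

Cumulative efficacy over $[t_0, t_n]$ is the duration-weighted average of
per-epoch efficacies with untreated gaps contributing zero. Measured slopes
are shifted to untreated equivalents by
$\mathrm{adj} = \mathrm{meas}/(1-\mathrm{Eff})$ for progressing patients
and $\mathrm{adj} = \mathrm{meas}\cdot(1-\mathrm{Eff})$ for improving ones;
at exactly zero the branches agree and the slope is unchanged. The
adjustment is an *upward shift* in both branches: treated patients would
have progressed faster, and improving patients improved partly because of
therapy.

## Longitudinal slopes

Exacerbation visits are excluded before anything else — relapse-associated
disability is largely transient and would inflate sustained-progression
estimates. Patients qualify with ≥3 computable-CombiWISE visits spanning
≥1 year or ≥2 spanning ≥3 years. Slopes are per-patient OLS of scale value
on age; $R^2$ is reported only when residual variation is defined (≥3
visits, nonconstant response), and constant-response patients are dropped
from the paired CombiWISE-vs-EDSS $R^2$ comparison with a logged count.
The paired comparison uses a two-sided paired $t$ interval; when the
differences are numerically constant the interval degenerates to the mean.

## Partitioning

The training/validation split stratifies on race, sex, and above/below
cohort-median bins of therapy-adjusted CombiWISE/age and first-visit age,
then draws $\lfloor 2n/3 + 0.5 \rfloor$ of each cell into training. Crossing
2 × 2 × 2 × 2 variables yields 16 cells, and that is what we implement;
the source description counts "12 groupings", which cannot be reconciled
with the variables as described, so we follow the procedure rather than
the count. Ties at the median go to the lower bin (configurable). The
stability check re-partitions fully at random and records the distribution
of validation correlations of retrained models.

## The severity model

MS-DSS is a gradient-boosted regression-tree ensemble predicting
therapy-adjusted CombiWISE slopes (units/year) from first-visit features.
Hyperparameters follow the study configuration: interaction depth 2,
shrinkage 0.001, half of the observations withheld from each tree, squared
error loss, tree count selected by five-fold cross-validation. The CV grid
is multiplicative (100 to 10,000 by factor 1.5 by default) — the source
states CV was used but not the grid. Relative influence is each feature's
share of the total squared-error split improvement across all trees,
normalised to 100; the reduced model retains exactly the features above
4% influence and is retrained on them.

The tree learner is xgboost, whose depth/shrinkage/subsample parameters map
one-to-one onto this configuration and which routes missing values natively
(absence branch learned per split). Missing COMRIS-CTD, unknown family
history, and never-treated therapy delay are therefore propagated as `NA`,
never imputed. The categorical therapy-type feature is encoded as an
integer code (0 none/unknown, 1 low only, 2 high only, 3 both) — with
depth-2 trees this is a mild restriction relative to true categorical
splits and the feature carries little influence in practice. MS-DSS is
reported in predicted CombiWISE-units/year; no rescaling to a 0–10
convention is applied because none is defined for it.

Training is deterministic given a seed and a single thread; models
serialise to the learner's portable format with a JSON metadata sidecar
(features, hyperparameters, influences, seed, versions).

## The synthetic cohort generator

No patient-level data ship with the package. `simulate_cohort()` emulates
the cohort the method targets:

* **Marginals** (truncated normals): first-visit age 48.6 ± 11.6 y on
  [23, 70]; onset age 37.1 ± 11.4 y (≥ 8, and before first visit);
  untreated-equivalent baseline CombiWISE 30.4 ± 17.5 on [0, 100];
  COMRIS-CTD 12.8 ± 6.3 (≥ 0, 10% missing); follow-up span 4.49 ± 2.90 y;
  ~50% female, ~88% white, ~60% smokers, family-history categories at the
  published cohort proportions. Parent parameters are moment-matched so the
  *truncated* draws carry the stated moments.
* **Latent structure**: each patient has a true untreated slope
  $s = -0.55 + 0.9\,\mathrm{CW}_0/\mathrm{age} + 0.05\,\mathrm{COMRIS}
  + 0.03\,\mathrm{delay} + \varepsilon$, with $\varepsilon$ a centred
  Gamma(2, 0.5) — right-skewed, leaving roughly 15% of patients improving.
  The couplings were chosen once so that the single-feature and model-based
  correlations with estimated adjusted slopes land in the published
  regime (≈ 0.3 and ≈ 0.4); they are configuration, not a claim about
  biology.
* **Forward model**: the latent CombiWISE trajectory is piecewise linear,
  progressing at $s(1-\mathrm{Eff})$ on treated segments (or
  $s/(1-\mathrm{Eff})$ for improving patients) — the exact inverse of the
  adjustment identities, so the pipeline's forward–backward consistency is
  testable to machine precision. Measured baseline CombiWISE is the
  untreated-equivalent baseline attenuated by pre-baseline treatment.
  Visit targets add Gaussian measurement noise (default sd 2 CombiWISE
  units) and a transient +8 bump at exacerbation visits (5% of visits), so
  the exclusion rule is testable end-to-end.
* **Component decomposition**: per visit, EDSS is drawn on its legal grid
  near a disability-matched value, the peg time on a realistic curve, SNRS
  solved and rounded to its integer grid, and the walk time absorbs the
  remaining residual in closed form — so recomputing the composite from the
  emitted components reproduces the visit target to machine precision.
  Targets are clamped to [1, 95] to stay within the decomposable range;
  exact slope-recovery identities accordingly hold only for trajectories
  off the scale floor/ceiling, and the tests restrict themselves to those.

What the generator does **not** emulate: relapsing–remitting biology beyond
the exacerbation bump, MRI acquisition, dependencies among the four
component scales beyond composite consistency, informative missingness,
or treatment-by-indication (treatment assignment is independent of the
latent slope). Passing tests therefore demonstrate the pipeline's internal
consistency and its behaviour under the assumed structure — not clinical
validity on real cohorts.

## Problem sizes

The test suite works at cohort sizes 25–201 with 3,600 composite-oracle and
efficacy-oracle random cases, 1,000 forward–backward pairs, 500-patient
slope-recovery runs, 50-seed split-contract checks, and a 20-seed
end-to-end scale-comparison experiment (201 patients each, 2,000-tree
models). The acceptance script runs one full 201-patient pipeline with the
default 10,000-tree CV grid plus a 60-replicate stability analysis. These
sizes keep full runs in the minutes range while leaving every assertion
comfortably powered.

## Known limitations

* Local MSSS/ARMSS referencing (above) differs from the published global
  tables; correlations involving them are cohort-relative.
* The efficacy adjustment treats the two-class age-linear model as exact
  and drug identity within a class as exchangeable; per-drug effects,
  dose, and adherence are out of scope.
* The adjustment identities assume multiplicative, immediate, and constant
  within-epoch treatment effects; delayed onset or carry-over effects are
  not modelled.
* MS-DSS trained on one cohort is not calibrated for another without
  re-deriving the reference scales and re-training; the package exposes the
  full pipeline precisely so that this is mechanical.
* The model is undefined for pediatric-onset patterns (the age–efficacy
  lines and the age marginals are adult-cohort constructs).
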
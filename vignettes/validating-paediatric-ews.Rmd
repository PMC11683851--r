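---
title: "Validating paediatric early warning scores in a weighted, stratified cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating paediatric early warning scores in a weighted, stratified cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pewsval)
```

## The validation problem

A paediatric early warning score is a sum of integer points over admission
clinical signs; validating one means asking how well that sum separates
children who die in hospital from those who survive. This package
validates eleven score entries (ten scores; PEDIA has separate early and
late forms) in cohorts with a deliberately unbalanced sampling design:
children are enrolled 2:1:2 across three nutritional strata — no wasting,
moderate wasting, and severe wasting or kwashiorkor — defined from
mid-upper arm circumference (MUAC), age and bipedal nutritional oedema.
Because malnourished children are heavily over-sampled relative to a
general admitted population, every full-cohort estimate carries a
population weight; within-stratum analyses are unweighted.

## Score calculators

Score definitions are data, not code: `inst/extdata/scores.yaml` declares,
per score, the range, the predefined cutoff (where the original
publication fixed one), an applicability predicate (RISC applies only to
HIV-negative children), an optional design syndrome (LODS for malaria,
RISC and RISC-Malawi for lower respiratory tract infection), and the
items. An item predicate is a comparison (`lt`,`le`,`gt`,`ge`,`eq`,`in`)
on one patient field, optionally age-banded (`value_by_age`), or an
`all`/`any` composite. Items sharing a `group` are mutually exclusive
levels of one sub-scale, and the registry validator requires the
attainable maximum (ungrouped points plus per-group maxima) not to exceed
the declared range.

Three adaptations reflect fields a multi-site admission dataset typically
has: "shock"-type items use capillary refill >3 s plus age-specific
tachycardia (infant >160 bpm, 12–23 months >150 bpm) rather than blood
pressure or pulse quality; the Brighton PEWS capillary-refill sub-scale is
remapped to the three recorded levels (2–3 s → +1, >3 s → +2); and its
post-operative vomiting item is encoded with the `never` operator because
surgical admissions are excluded. Consciousness is a single
AVPU-like four-level field; scores written against the Blantyre Coma Scale
are mapped through predicates on it ("coma" = responds to pain or
unresponsive). The supplementary item-level tables of the validation study
are not public, so item points are transcribed from the original score
publications onto these fields; they are faithful in structure (ranges,
cutoffs, adaptations, applicability) but individual point values should be
reviewed against the originals before any clinical use.

**Missing data.** The default `missing_behavior` is *score-zero*: an
unrecorded sign contributes no points, matching bedside practice where an
item that cannot be assessed is not scored. `propagate` is available per
item for stricter analyses; the number of items with missing inputs is
reported alongside every total so users can filter on completeness.

**Boundary conventions.** All "at or above threshold" predicates are
closed on the printed threshold; hypoxaemia is strict (`SpO2 < 90%`).
High-risk classification is `score ≥ cutoff` — the convention that
reproduces published confusion-count patterns where the cutoff row itself
counts as positive.

## The validation engine

The primary metric is the weighted Mann–Whitney AUC: the probability that
a random case outranks a random control, with each child contributing its
population weight,

$$\mathrm{AUC} = \frac{\sum_{i \in D}\sum_{j \in S} w_i w_j\,[\,\mathbf{1}(s_i > s_j) + \tfrac12 \mathbf{1}(s_i = s_j)\,]}{\left(\sum_{i \in D} w_i\right)\left(\sum_{j \in S} w_j\right)}.$$

It is computed by one sort over distinct score values (cumulative control
weight below each value plus half the tied weight), which is O(n log n)
and agrees with the brute-force double sum to machine precision — a
property the tests check on hundreds of random tied, weighted instances.
With unit weights it reduces to the usual ROC AUC, cross-checked against
pROC. Two consequences worth knowing: multiplying all weights by a
constant changes nothing, and on tie-free data AUC(s) + AUC(−s) = 1.

Confidence intervals use a seeded percentile bootstrap over children
(weights carried with the resampled child), default 2000 replicates in the
engine and 200–500 in the bundled drivers; replicates that lose one
outcome class are redrawn with a retry guard. The percentile bootstrap was
chosen because it is valid for weighted AUCs without further derivation;
DeLong-type variances would need a survey-weighted extension. AUCs are
labelled with the conventional interpretation bands (≥0.8 excellent,
0.7–0.8 acceptable/good, 0.5–0.7 poor, <0.5 not useful; lower edges
closed).

For scores without a predefined cutoff the operating point maximises
Youden's J = sensitivity + specificity − 1 over every integer cutoff from
the range minimum to range maximum + 1 (the last classifies nobody as
positive); ties take the lowest cutoff, favouring sensitivity. Secondary
metrics come from the weighted confusion counts at the chosen cutoff, with
likelihood ratios computed from unrounded proportions; PPV/NPV are flagged
undefined rather than invented when their denominator is zero. Rounding
(2 dp; PPV/NPV as percentages) happens only at the reporting edge.

Full-cohort analyses use the population weights; per-stratum, per-site and
per-age-band panels are unweighted; disease-restricted analyses inherit
the weighting of their enclosing population. No multiplicity correction is
applied — reports show CIs, not adjusted p-values. A subgroup filter that
removes every case or control yields an explicit not-evaluable row.

## The synthetic cohort generator

The generator emulates the *design* the engine assumes, not any real
cohort's covariance structure:

* **Enrolment**: default n = 3101 children, ages 2–23 months (integer
  months, uniform), 9 sites, exact-quota 2:1:2 strata (largest-remainder
  apportionment; a multinomial option exists).
* **Anthropometry**: MUAC is drawn uniformly inside the assigned stratum's
  age-specific interval, so stratum assignment round-trips exactly;
  kwashiorkor (30% of the severe stratum) frees MUAC from its interval.
  Weight-for-age Z is centred at −0.5/−2.2/−3.3 by stratum (SD 0.8).
* **Severity**: a latent standard normal per child plus stratum
  (0/0.2/0.4) and site (SD 0.3) shifts, centred. Every binary sign is
  Bernoulli with a logit-linear dependence on severity; consciousness and
  capillary refill are proportional-odds ordinals; SpO2, heart rate,
  respiratory rate and temperature are truncated normals with
  severity-shifted means. This is the simplest structure that makes every
  score discriminative, which is all the pipeline's correctness tests
  need.
* **Death**: logit-linear in severity with slope `severity_effect`
  (default 1.0). The per-stratum intercept is calibrated by root-finding
  on the realized severity draws so the expected stratum mortality equals
  the configured 3.5%/8.1%/20.4% for any slope; with slope 0 it reduces to
  the plain logit of the target rate. Day of death is geometric with a
  severity-raised daily hazard (baseline 0.40/day), so roughly three
  quarters of deaths fall within the first 48 hours and the earliest
  deaths are the sickest children — which is why fixed-horizon AUCs at day
  2 are at least as high as at day 30 in the bundled analyses. Survivors
  get a later geometric discharge day.
* **Weights**: `target_proportions[s] / sample_proportion[s]` per stratum.
  The reference population split is **not** published for the motivating
  study; the default 80/10/10% (no/moderate/severe) is a deliberately
  arbitrary but plausible general admitted population, and is a config
  input. Weighted stratum shares reproduce the target exactly and the mean
  weight is 1 by construction.
* **Missingness**: each missable measurement (vitals, refill, WAZ, two
  auscultation signs) is independently absent with probability 0.02 —
  enough to exercise the missing-data policy without dominating results.

What it does **not** emulate: real between-sign correlation beyond the
shared severity factor, site case-mix differences beyond a severity shift,
post-discharge follow-up, seasonality, or household covariates. Passing
tests on synthetic cohorts therefore demonstrates the *pipeline* is
correct (weights, metrics, cutoffs, conservation, reproducibility), not
that any score performs at any particular level in real children; the
synthetic AUCs printed by the drivers describe the simulator only.

## Numerical and design choices

* Stratum boundaries are half-open: MUAC exactly 12.5 cm (12.0 cm under
  6 months) is "no wasting", 11.5 (11.0) is "moderate" — making the three
  categories a partition of all valid inputs.
* The weighted-AUC tie term is exactly ½, and the rank path is required
  (by test) to match the brute-force definition to 1e-12.
* Bootstrap and simulation randomness flow from explicit integer seeds;
  generated cohorts and written reports are byte-identical under a
  repeated seed, and the generator restores the caller's RNG state.
* Degenerate inputs fail loudly before computation: empty registries,
  inflated item maxima, nonpositive MUAC or weights, outcome vectors with
  one class, bootstrap replicates that cannot be balanced.
* Test problem sizes were chosen to keep the full suite under a minute on
  one core while leaving Monte-Carlo checks well-powered: 10^4 random
  patients for range safety, 10^4 children for mortality recovery (3
  binomial SE bands), 500 random instances for oracle equivalence, 100
  seeded repetitions (n = 2000, 200 bootstrap replicates) for CI coverage
  against the generator's n = 10^5 large-sample AUC.

## Known limitations

Item-level points are reconstructions where the original supplementary
mapping is not public (see above). The bootstrap CI is percentile-only;
BCa and survey-weighted DeLong variants are out of scope. Calibration
(observed vs predicted risk) is deliberately not assessed — the engine
measures discrimination only. Fixed-horizon outcomes count any death with
a known day on or before the horizon; restricting to inpatient deaths is a
flag on `outcome_at_horizon()`, since whether published horizon analyses
include post-discharge deaths is generally unstated.
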
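---
title: "Methods: incidence-based YLD estimation for burn injuries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incidence-based YLD estimation for burn injuries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnyld)
```

## The problem

Burden-of-disease accounting expresses the non-fatal consequences of injury
as years lived with disability:

$$\mathrm{YLD} = \text{incident cases} \times \text{disability weight}
  \times \text{duration (years)}.$$

Generic injury disability weights fit burns poorly: outcomes after a burn
range from full recovery within weeks to lifelong impairment, and recovery
unfolds over roughly two years rather than the single 12-month horizon used
by conventional methods. `burnyld` implements an incidence-based pipeline
adapted to that recovery profile:

1. **Severity grouping.** Patients are partitioned by burned body surface
   area into three groups with comparable outcomes: <5% TBSA (or %TBSA
   missing), 5–20% TBSA, >20% TBSA. %TBSA is recorded in every burn
   registry, so the grouping is portable.
2. **Empirical disability weights.** The disability weight of one
   EQ-5D-3L observation is the age/sex general-population norm utility
   minus the patient's utility. Weights are aggregated per severity group
   in five recovery windows — 0–1, >1–6, >6–12, >12–24 and >24 months
   post-burn — as arithmetic means with 95% confidence intervals.
3. **Lifelong disability.** A patient is classified as having lifelong
   disability when the two-year assessment reports a severe (level 3)
   problem in any dimension, or mild problems (level ≥ 2) on both
   pain/discomfort and anxiety/depression. Group-level proportions of
   lifelong disability feed the long-term YLD term.
4. **YLD computation.** Short-term YLDs multiply group incidence by each
   short-term window's weight and duration (1/12, 5/12, 6/12 and 1 year —
   the four durations sum to the 2-year short-term horizon). Long-term
   YLDs multiply incidence by the lifelong proportion, the >24-month
   weight and the remaining life expectancy minus 2 years.

## Utility scoring

Health states are EQ-5D-3L profiles: five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression) at three levels,
serialized as 5-digit codes. The embedded tariff is the UK
general-population time trade-off value set — an additive model with an
any-dysfunction constant (0.081), per-dimension level-2/3 decrements, and
an any-level-3 constant (0.269). It anchors full health at 1, death at 0,
and reaches −0.594 at the all-threes state; a single UK tariff is used
because multi-country cohorts rarely all have national value sets.

```{r tariff}
score_utility(c("11111", "21111", "21232", "33333"))
```

Scoring is monotone: a state that is level-wise worse in every dimension
never scores higher. The test suite asserts this over all 243 × 243
comparable state pairs, together with the bounds above.

### Population norms

Disability weights need an age- and sex-specific reference. Norms are a
band-lookup table (no interpolation: published norm tables are themselves
band means, and interpolating would manufacture precision the source data
do not have). The packaged default covers ages 18–100 for both sexes with
values shaped like UK general-population norms (≈0.94 in young adults
declining to ≈0.71–0.75 beyond 75). **The default table is illustrative**:
the norm survey behind the published weights is not reproduced here, so
real analyses should load their own table with `read_norm_table()`.

### Crosswalks

Multi-instrument cohorts (SF-36, EQ-5D-5L) are mapped onto the 3L
instrument through generic response-mapping machinery: per target
dimension, a multinomial model yields level probabilities; the expected
utility weights every tariff decrement by its level probability and the
two constants by their event probabilities (algebraically identical to the
brute-force expectation over all 243 states, which the tests verify).
A modal-state mode returns the per-dimension most likely level, ties
resolving to the less severe level. Published coefficient sets are
accepted as input tables, not shipped.

## Aggregation choices

* **Pooling level.** By default every observation counts once
  (observation-level pooling), matching how the source registries count
  outcomes; patient-level pooling (average within patient and window
  first) is available via `level = "patient"` for sensitivity analyses.
* **Confidence intervals.** Mean ± 1.96·SE by default. The published
  tables print symmetric intervals without naming a method, and at the
  cell sizes involved (hundreds to thousands of observations) normal
  theory is adequate; Student-t and a seeded percentile bootstrap are
  provided as alternatives.
* **Negative weights are kept.** Patients above their population norm get
  negative disability weights; truncating them at zero would bias cell
  means upward.
* **Empty cells are absent, not zero.** A cell with no observations
  propagates as missing and must be filled from the embedded published
  table before YLD computation.
* **Boundary conventions.** 5% and 20% TBSA belong to the middle severity
  group (the inclusive reading of the "5–20%" label); recovery windows are
  half-open on the left and closed on the right, so 24.0 months is still
  short-term. Exactly-boundary months and percentages are rare in practice
  but the convention is pinned by tests.

## Embedded published constants

Because the pooled 7159-observation cohort behind the published weights is
not redistributable, the package embeds the published results as defaults:
the 15-cell disability-weight table (`default_dw_table()`), the lifelong
proportions 20%/25%/39% (`default_lifelong_proportions()`), and the 2017
country results (`published_yld_2017()`) used for validation. YLD runs on
incidence-only input therefore reproduce the published methodology with
its published parameters; every default use is logged by the CLI.

## The YLD engine

`compute_yld()` accepts incidence per (country, year, severity group),
optionally stratified by sex and age. Remaining life expectancy comes
either from a life table (stratified input) or from an explicit
per-country scalar at the mean age at injury — there is deliberately no
hidden default, since the long-term term is linear in the remaining life
expectancy and the age distribution of cases is a first-order input.
"Remaining life expectancy minus 2 years" is floored at zero. Registry
small-cell censoring (counts reported only as "between one and five") is
resolved by the assumed average of 2, encoded as the literal token `"1-5"`
in input files.

Per-100,000 rates divide country YLD totals by user-supplied population
denominators. The published per-100k figures used a denominator that
cannot be reconstructed from national populations, so the package never
claims to reproduce them; `demo_population_2017()` provides round national
figures for illustration only.

Report rounding (totals to 1 decimal, per-case to 2, per-100k to 1) is
applied only at the writing stage; all internal arithmetic is full
precision.

## The synthetic cohort generator

Every stage is testable without access to patient data through a seeded
simulator. Its defaults are fixed to the cohort the pipeline was built
for: group sizes 1587/1364/450, age ~ Normal(41.1, 15.5²) truncated to
18–90 years, 70.9% male, and one scheduled assessment per recovery window
at 0.75, 3, 9, 18 and 60 months. True cell means default to the embedded
published table; utility noise defaults to sd 0.25, a realistic
within-cell spread for EQ-5D utilities in injured populations.

The trajectory model draws each observation's utility around
`norm(age, sex) − true_dw(group, window)` with the configured noise,
censored to the tariff bounds [−0.594, 1]. One numerical subtlety matters:
naively adding Gaussian noise and clamping at the full-health ceiling
inflates every mild-burn cell mean, because the ceiling clips the noise
asymmetrically (at sd 0.25 the inflation reaches ≈0.02–0.04 for the
mildest cells — larger than the estimation error at realistic cell sizes).
The generator therefore solves for the pre-censoring location at which the
censored normal has *exactly* the target mean (a monotone one-dimensional
root-find, memoised over the handful of distinct norm/weight
combinations). Generated cohorts are thus mean-faithful at any noise
level, and exactly invertible at `noise_sd = 0`.

Each observation also carries the EQ-5D-3L state whose tariff utility is
nearest the drawn utility (ties to the less severe state). This keeps the
utility-level and state-level pipeline paths consistent; it is a modelling
convenience, not a claim about real response patterns — real EQ-5D data
are discrete, skewed, and have mass exactly at full health, none of which
the Gaussian model reproduces. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real-world response distributions.

Attrition removes a patient's later assessments with a per-window
probability (a scalar stand-in for loss to follow-up; it does not emulate
outcome-dependent selection). Incidence generation draws Poisson counts or
returns configured rates verbatim, with optional small-cell censoring
emulation.

## Problem sizes and verification

The test suite verifies, among other properties: tariff bounds and
monotonicity by full enumeration (243 states); the lifelong classifier
against independent enumeration; Mann-Whitney U against a brute-force
pair-counting and permutation oracle for all combined sample sizes ≤ 8
(the package uses exact enumeration up to combined n = 10 — valid under
ties — and a tie-corrected normal approximation beyond, matching common
statistical-package behaviour); exact generator inversion at zero noise;
and an end-to-end noiseless run against a closed-form hand computation at
10⁻⁹ tolerance. Stochastic parameter recovery uses 500 observations per
cell and 100 seeded replicates, sizes at which one replicate runs in
about 0.2 s; nominal CI coverage at these sizes is ≈95%, so the ≥90%
coverage check carries a small (percent-level per cell) chance of a
false alarm under any fixed seed set.

## Known limitations

* The default norm table is illustrative, not the survey used for the
  published weights; absolute disability weights from the defaults should
  not be quoted against published values without supplying real norms.
* The published per-100k denominators are not reconstructible; per-100k
  output depends entirely on user-supplied populations.
* The lifelong classifier is applied to the assessment in the >12–24 month
  window closest to 24 months; patients with no such assessment are
  excluded rather than imputed.
* Whether exactly-5% and exactly-20% patients belong to the middle group
  is a convention (adopted: inclusive middle); registries with many
  round-valued %TBSA entries may be sensitive to it.
* The engine computes YLD only — years of life lost and full DALYs are out
  of scope, as is the prevalence-based YLD methodology.
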
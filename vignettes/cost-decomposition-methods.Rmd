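---
title: "Decomposing the incremental healthcare costs of cognitive impairment"
author: "costdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the incremental healthcare costs of cognitive impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costdecomp)
```

## The scientific question

Community-dwelling older adults with cognitive impairment incur substantially
higher total healthcare costs (THC) than their unimpaired peers, even after
accounting for demographics and comorbidity burden. Cognitive impairment,
however, travels together with two other geriatric syndromes — functional
impairment (difficulty with activities of daily living, ADLs) and frailty —
and both independently predict higher costs. `costdecomp` quantifies how much
of the *incremental* cost of cognitive impairment is routed through these
syndromes: if most of the excess is attributable to functional impairments
and frailty, interventions that target those (potentially modifiable)
syndromes could mitigate the excess cost.

The package is aimed at health-services and epidemiology researchers working
with participant-level cohort tables linked to claims-derived cost outcomes
(one row per participant: demographics, cognitive measures, frailty
component measurements, ADL difficulty flags, condition flags, follow-up,
death, cumulative cost).

## Phenotype harmonization

All analysis variables are derived from raw measures with harmonized rules:

* **Cognitive impairment** (the exposure): a self- or proxy-reported
  clinician diagnosis of dementia, *or* a cognitive test score at least 1.5
  SD below the education-stratified (`< 9`, `9–12`, `> 12` years) mean of
  adults aged 65–69. The young age band limits contamination of the norms by
  prevalent dementia. The boundary is read inclusively (`score <= mean −
  1.5·SD` qualifies); the source text does not fix inclusivity, so we chose
  the literal reading of "at least" and made the multiplier configurable
  (`n_sd`). An alternative NHATS-style rule is provided: diagnosis with a
  proxy AD8 score `> 2`, or at least two of three impaired cognitive domains
  (domain flags are consumed precomputed; instrument-level scoring is out of
  scope).
* **Norms** default to being estimated from the supplied cohort's
  65–69-year-olds per education stratum, and can be overridden with fixed
  published values — synthetic cohorts carry their generating norms as an
  attribute so classification round-trips exactly.
* **Functional impairments**: count (0–4) of self-reported difficulty
  walking a few blocks, climbing steps, transferring bed to chair, and
  bathing/showering; modelled as a 5-level categorical with 0 as referent.
* **Phenotypic frailty**: five components — shrinking (weight loss ≥ 5% or
  ≥ 10 lb, or BMI < 18.5), weakness (grip < 32 kg men / < 20 kg women), poor
  energy, slowness (gait < 0.8 m/s men / < 0.6 m/s women, or walking aid),
  low activity. Component inequalities are strict exactly as printed; 0
  components = robust (referent), 1–2 = pre-frail, ≥ 3 = frail.
* **CFI**: a claims-based deficit-accumulation frailty index consumed as a
  continuous value in [0, 1]; the claims-code algorithm is out of scope.
* **Comorbidity**: count of chronic conditions against a sex-specific
  vocabulary (12 conditions for women, 11 for men; sex-specific cancers
  differ). A CMS-HCC risk score may be supplied as an alternative adjuster;
  it is used only in sensitivity analysis because its algorithm includes
  dementia codes.

Any record missing a required phenotype input is flagged and excluded before
modelling, ahead of the enrollment screen; the exclusion report preserves
this ordering because the counts are order-dependent.

## Cost outcome

The outcome is standardized annualized THC over the 36 months after the
index exam: cumulative cost divided by follow-up in years, with follow-up
truncated at death, so decedents' costs are spread over observed exposure
only. Survivors must carry the full 36 months; records with zero exposure
cannot be annualized and are excluded with a logged reason. An inflation
table (year → multiplier, anchored at 1 in 2023) standardizes costs to 2023
dollars; component columns (hospital, SNF, outpatient, DME, home health) may
be supplied pre-summed or separately. Note that annualization at death can
overstate person-year costs for decedents — a known property of this
estimand, not a bug.

## The cost model and margins

Costs are right-skewed and strictly positive, so mean costs are modelled
with a generalized linear model with **log link and gamma variance**,
fitted by iteratively reweighted least squares (tolerance `1e-10` on the
relative deviance change, up to 100 iterations; rank-deficient designs fail
with the aliased columns named). The gamma family excludes zero outcomes;
the default rule replaces a zero cost with $1 (configurable: shift-all or
exclude), and adjusted counts are recorded on the fit. Dispersion is
estimated by Pearson chi-square over `n − p`; it affects neither the point
estimates nor the margins.

Covariate codings are the conventional choices and are overridable: age
linear, race 3-level (reference non-Hispanic White), region categorical
(reference first alphabetically), comorbidity count linear, ADL category
0–4 (reference 0), frailty category (reference robust), CFI linear.
Education is *never* allowed as a covariate, because educational level is
part of the exposure definition; the configuration validator rejects it.

Adjusted group means come from **marginal standardization (recycled
predictions)**: predict every participant's cost with exposure forced to 1,
then to 0, and average each set of predictions. This is the standard
"margins" approach for cost standardization (predictive margins, not
margins-at-means). The incremental cost is the difference of the two
averages, exactly.

## Difference-method decomposition

For each explanatory set *M* (ADL category, frailty category, CFI, or all
three):

* **total** = incremental cost from the base model (exposure + age, race,
  region, comorbidity);
* **direct** = incremental cost from the base model further adjusted for
  *M*;
* **indirect** = total − direct, the share of the incremental cost
  attributable to *M*. Additivity holds exactly by construction, and the
  indirect share is `100 · indirect / total` (undefined, flagged, when the
  total is not positive).

This is the regression difference method, not a causal-mediation estimand:
no exposure–mediator interactions are modelled, and the components should be
read as covariate-adjustment attributions.

Confidence intervals are **percentile bootstrap** (default `B = 1000`):
participants are resampled with replacement (within sex strata when pooled
data are supplied, since every primary analysis is sex-stratified), both
models are refitted per replicate, and 2.5th/97.5th percentiles are taken
per component. The indirect interval is computed from replicate-wise
`total − direct`, preserving the within-replicate correlation of the two
fits. Phenotypes and covariate codings are fixed before resampling (costs
are decomposed *given* phenotypes; norms are not re-estimated per
replicate). Per-replicate seeds are drawn once from the spec seed, making
results reproducible and order-independent; replicates are warm-started at
the point-estimate coefficients, which changes nothing but iteration
counts. Failed replicates are dropped and counted, with a warning above 5%.
Share CIs are derivable from the stored replicate matrix but are not
printed by default.

Sex-pooled sensitivity estimates combine the female and male results
component-wise with equal or size-proportional weights; when both results
carry replicate matrices the intervals are recomputed on the weighted
replicates, otherwise endpoints are weighted directly and flagged
approximate.

## The synthetic cohort generator

No deposited cohort with linked claims costs is publicly available, so the
package ships a generator (default preset `"medicare-like"`) whose defaults
emulate the published cohort structure, and against which the whole pipeline
is validated:

* sex-specific cohorts (defaults n = 4318 women, 3847 men), truncated-normal
  age (women mean 80, SD 6.5; men 78.4, 6.0, minimum 65);
* cognitive impairment from a logistic model in age and race whose intercept
  is **calibrated by numerical integration** (quadrature over the age
  distribution and race mixture) to hit the target prevalence of 12.1%
  (women) / 10.9% (men) by construction;
* mediators conditional on impairment only: ADL count via an ordinal logit
  (impairment shift +1.4 on the cumulative log-odds), the five frailty
  components via per-component Bernoulli draws (+0.65 log-odds under
  impairment), CFI via a beta distribution (women: mean 0.16 → 0.21 under
  impairment, matching the descriptive contrast);
* death within 36 months at 0.326 vs 0.106 (women, impaired vs not; men
  0.316/0.109), decedent follow-up uniform on (0, 36] months;
* annualized cost gamma-distributed (shape 0.5, so the marginal cost
  distribution is strongly right-skewed) with log-linear mean: direct
  exposure effect 0.18–0.20 log-dollars, ADL category effects 0–0.60,
  frailty category 0–0.30, CFI 1.8, plus age, race, region, and comorbidity
  terms; baseline chosen so unimpaired mean annualized THC is near $14,000.

Raw measures are emitted consistent with the drawn statuses (grip strength
below the sex threshold iff weakness was drawn, test score below the
education-stratified cutoff iff impaired without diagnosis, and so on), so
phenotyping recovers the generative truth exactly — this round trip is
asserted in the tests. Mediators are drawn independently of age and race
given impairment status, and independently of each other; real cohorts have
richer mediator correlation with demographics and with each other, so
passing tests validate the estimator's statistical behaviour, not the
realism of any particular joint distribution. Claims-level utilization
events and cost components are not simulated. The `"null"` preset removes
all exposure effects (and randomizes the exposure); `"pure-mediation"`
removes only the direct effect.

### The g-computation oracle

`decomposition_oracle()` computes the generative truth by Monte-Carlo
g-computation on the model itself: the true total is
`E[cost | do(CI=1)] − E[cost | do(CI=0)]` with mediators from their
CI-conditional laws, and the true direct effect holds the explanatory set's
mediators at their CI = 0 law (mediators outside the set still follow CI).
Expected costs, not sampled ones, are averaged, and the Monte-Carlo SE is
reported. Under a log link the difference-method estimand and this
mediational contrast coincide only approximately — the adjusted model's
margins average mediators over the cohort mixture rather than the CI = 0
law — so validation compares the estimator to the oracle within Monte-Carlo
tolerance rather than demanding equality. With the shipped presets
(impairment prevalence ≈ 12%) the gap is small relative to sampling error at
the validation sample sizes.

## Validation design and problem sizes

The test suite validates, among other properties: exhaustive truth-table
equivalence of the frailty classification (all 32 component patterns);
monotonicity of the classifiers; closed-form recovery of group means by the
saturated gamma fit; coefficient recovery within 3 SEs at n = 5,000;
agreement of the margins with a brute-force per-row prediction oracle at
`1e-10` relative tolerance; agreement of the estimated total with the
g-computation truth within 3 Monte-Carlo SEs at n = 20,000; collapse of the
indirect (respectively direct) component under the null-mediation
(pure-mediation) preset; and 95% bootstrap interval coverage of the oracle
indirect effect across 200 simulated cohorts (n = 2,000, B = 300, CFI
explanatory set — sizes chosen to keep the full coverage study at desk
scale while leaving coverage estimation error near ±1.5 points). Published
worked examples (the exclusion cascade, prevalence, components and shares)
are reproduced by the reporting code at printed precision: percentages to
one decimal, dollars to the nearest integer.

## Numerical and degenerate-input choices

* Zero-cost outcomes: floored at $1 by default (logged); the gamma support
  guard errors when zeros survive the rule.
* Zero or negative follow-up: excluded with a reason — a death on day 0
  carries no exposure to annualize.
* Empty factor levels inside a bootstrap resample produce identically zero
  design columns; their coefficients are set to zero (they cannot affect
  within-resample predictions). Any other aliasing fails the replicate,
  which is dropped and counted.
* Resamples with a constant exposure column fail the replicate fit rather
  than silently producing a degenerate contrast.
* A non-positive total makes the indirect share undefined; it is flagged,
  not thrown.

## Limitations

The difference method attributes costs by covariate adjustment; it does not
identify natural direct/indirect effects under exposure–mediator
interaction. ADL, frailty, and CFI overlap as constructs, so single-set
attributions are not additive across sets. The generator matches the
published descriptive margins and directions, not the unknown joint
distribution of mediators; survey weighting, claims ingestion, and
condition-flag algorithms (CCW, CMS-HCC, CFI) are out of scope — those
scores enter as supplied columns.
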
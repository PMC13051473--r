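# costdecomp

Older adults with cognitive impairment cost the healthcare system
substantially more per year than their cognitively intact peers, even after
adjusting for demographics and comorbidity. How much of that incremental
cost travels through two co-occurring geriatric syndromes — functional
impairment and frailty? `costdecomp` is an R package for answering this
question on participant-level cohort data linked to claims-derived costs:
it harmonizes the phenotypes, annualizes death-truncated costs, fits gamma
log-link marginal cost models, and decomposes the incremental cost of
cognitive impairment into direct and indirect components with bootstrap
confidence intervals. A synthetic Medicare-like cohort generator with a
known generative truth is included for validation and demonstration.

## The method in brief

For annualized total healthcare costs *Y* (strictly positive, right-skewed),
binary cognitive-impairment status *D*, base covariates *X* (age, race,
region, comorbidity count), and an explanatory set *M* (ADL impairment
category, phenotypic frailty category, claims-based frailty index CFI, or
all three):

1. Fit gamma GLMs with log link, `E[Y] = exp(β₀ + β_D D + Xᵀβ)`, without and
   with *M*.
2. Marginal standardization (recycled predictions / "margins"): average each
   participant's predicted cost with *D* forced to 1 and to 0; the
   difference of the averages is the adjusted incremental cost.
3. Difference-method decomposition:
   - **total** = incremental cost from the base model,
   - **direct** = incremental cost after additionally adjusting for *M*,
   - **indirect** = total − direct (share: `100·indirect/total`).
4. Percentile-bootstrap 95% CIs, resampling participants (sex-stratified for
   pooled data) and refitting both models per replicate.

All analyses are sex-stratified; sensitivity analyses substitute the CMS-HCC
score for the comorbidity count and pool the sex strata with equal or
size-proportional weights.

## Worked example

```r
library(costdecomp)

# a medicare-like synthetic cohort of 4318 women with known generative truth
cohort <- generate_cohort(generative_params("medicare-like", "female", seed = 42))
cohort <- add_annualized_costs(phenotype_cohort(cohort))

spec <- decomposition_spec("all_three", n_reps = 400, seed = 7)
bootstrap_decomposition(cohort, spec)
#> Decomposition [all_three]
#>   total       12205 (8560, 15921)
#>   direct       4619 (1756, 7614)
#>   indirect     7587 (5867, 9420)
#>   indirect share 62.2% of total

decomposition_oracle(attr(cohort, "generative_params"), "all_three")
#> Generative truth [all_three]: total 9345.8, direct 2931.2, indirect 6414.7 (mc_se 25.7)
```

Reading the output: in this simulated cohort the covariate-adjusted
incremental annualized cost of cognitive impairment is about $12,200 per
person-year (this draw sits high of the generative truth of ~$9,400 — single
cohorts are noisy; the bootstrap interval conveys that). About 62% of the
incremental cost is attributable to the participant's ADL impairments,
frailty category, and CFI jointly (the indirect component); the remainder
persists after adjusting for all three (direct).

The full pipeline — exclusion cascade, descriptive table, the four-way
decomposition suite, both sensitivity analyses, and CSV/JSON/figure output —
runs from a configuration list or YAML file:

```r
report <- run_analysis(list(preset = "medicare-like", seed = 1,
                            bootstrap = list(n_reps = 1000, seed = 2),
                            output_dir = "out/"))
```

A thin command-line wrapper ships in `inst/exec/costdecomp`
(`generate`, `run`, `describe` subcommands).

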
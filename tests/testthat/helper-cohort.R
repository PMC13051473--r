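# Fixtures shared across the test files. Everything is built in code; no
# data files are read.

toy_norms <- function() {
  reference_norms_table(c("lt9", "9to12", "gt12"), c(90, 90, 90), c(6, 6, 6))
}

# One participant row with sensible defaults; override any field via ...
make_participant <- function(...) {
  row <- list(
    id = "p1", sex = "female", age = 78, race = "nh_white", region = "midwest",
    education = "9to12", cog_score = 92, dementia_dx = FALSE, ad8 = 0L,
    dom_memory = FALSE, dom_orientation = FALSE, dom_executive = FALSE,
    weight_loss_pct = 1, weight_loss_lb = 2, bmi = 26, grip_kg = 25,
    poor_energy = FALSE, gait_ms = 0.9, walking_aid = FALSE,
    never_walks_and_no_mvpa = FALSE,
    adl_walk = FALSE, adl_climb = FALSE, adl_transfer = FALSE, adl_bathe = FALSE,
    conditions = "", hcc_score = 1.0, cfi = 0.15,
    followup_months = 36, died = FALSE, cumulative_cost = 30000,
    continuously_enrolled = TRUE
  )
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

make_cohort <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_participant(id = paste0("p", i), ...)))
}

# Small phenotyped + costed synthetic cohort for model-level tests.
analysis_cohort <- function(preset = "medicare-like", sex = "female", n = 1500,
                            seed = 42) {
  coh <- generate_cohort(generative_params(preset, sex, n, seed = seed))
  add_annualized_costs(phenotype_cohort(coh))
}
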
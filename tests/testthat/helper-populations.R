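# fixture populations built in code ---------------------------------------

# two-stratum population: physical activity confounds the
# hypertension-disease association, constant stratum RR 1.5
table1_pop <- function() {
  stratified_population(tibble::tibble(
    stratum    = c("high_activity", "high_activity", "low_activity", "low_activity"),
    exposure   = c(0L, 1L, 0L, 1L),
    proportion = c(0.5, 0.3, 0.05, 0.15),
    risk       = c(0.1, 0.15, 0.2, 0.3)
  ))
}

# effect-modification variant: same proportions, exposed low-activity risk
# raised to 0.6 so the stratum RRs are 1.5 and 3
table1_em_pop <- function() {
  stratified_population(tibble::tibble(
    stratum    = c("high_activity", "high_activity", "low_activity", "low_activity"),
    exposure   = c(0L, 1L, 0L, 1L),
    proportion = c(0.5, 0.3, 0.05, 0.15),
    risk       = c(0.1, 0.15, 0.2, 0.6)
  ))
}

# exposure independent of the confounder (same prevalence in every stratum)
no_confounding_pop <- function(p = 0.4) {
  make_population(population_spec(
    stratum_weights = c(0.7, 0.3),
    baseline_risks = c(0.1, 0.25),
    stratum_rrs = 1.8,
    exposure_prevalence_by_stratum = c(p, p)
  ))
}

# risks identical across exposure levels within every stratum
null_effect_pop <- function() {
  make_population(population_spec(
    stratum_weights = c(0.6, 0.4),
    baseline_risks = c(0.1, 0.3),
    stratum_rrs = 1,
    exposure_prevalence_by_stratum = c(0.2, 0.7)
  ))
}

random_pop <- function(effect_modification = FALSE, n_strata = NULL) {
  if (is.null(n_strata)) n_strata <- sample(1:4, 1)
  make_population(random_population_spec(n_strata, effect_modification))
}
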
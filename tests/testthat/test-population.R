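test_that("construction validates proportions, duplicates and reference cells", {
  df <- tibble::tibble(
    stratum = c("a", "a", "b", "b"),
    exposure = c(0L, 1L, 0L, 1L),
    proportion = c(0.5, 0.3, 0.05, 0.15),
    risk = c(0.1, 0.15, 0.2, 0.3)
  )
  expect_s3_class(stratified_population(df), "stratified_population")

  bad_sum <- df
  bad_sum$proportion[1] <- 0.4
  expect_error(stratified_population(bad_sum),
               class = "pafbias_error_invalid_population")
  renorm <- stratified_population(bad_sum, normalize = TRUE)
  expect_equal(sum(renorm$proportion), 1)

  dup <- df
  dup$exposure[2] <- 0L
  expect_error(stratified_population(dup),
               class = "pafbias_error_invalid_population")

  no_ref <- df[df$stratum != "b" | df$exposure != 0L, ]
  no_ref$proportion <- no_ref$proportion / sum(no_ref$proportion)
  expect_error(stratified_population(no_ref),
               class = "pafbias_error_missing_reference",
               regexp = "b")

  neg <- df
  neg$risk[1] <- -0.1
  expect_error(stratified_population(neg), class = "pafbias_error_domain")
})

test_that("constant-RR population reproduces the textbook summary quantities", {
  pop <- table1_pop()
  expect_equal(observed_risk(pop), 0.15)
  expect_equal(counterfactual_risk(pop), 0.12)
  expect_equal(paf_definition(pop)$estimate, 0.2)
  expect_equal(exposure_prevalence(pop), 0.45)
  expect_equal(case_prevalence(pop), 0.6)
  expect_equal(unadjusted_rr(pop), 11 / 6)
  expect_equal(marginal_causal_rr(pop), 1.5)
  # constant stratum RRs: exposed-restricted causal RR equals the marginal one
  expect_equal(causal_rr_exposed(pop), 1.5)
  expect_equal(stratum_causal_rrs(pop)$rr_c, c(1.5, 1.5))
})

test_that("effect-modification variant reproduces its summary quantities", {
  pop <- table1_em_pop()
  expect_equal(observed_risk(pop), 0.5 * 0.1 + 0.3 * 0.15 + 0.05 * 0.2 + 0.15 * 0.6)
  expect_equal(counterfactual_risk(pop), 0.12)
  expect_equal(paf_definition(pop)$estimate, 0.075 / 0.195)
  expect_equal(marginal_causal_rr(pop), 2)
  expect_equal(causal_rr_exposed(pop), 2.25)
  expect_equal(unadjusted_rr(pop), 0.3 / (10 / 11 * 0.1 + 1 / 11 * 0.2))
  expect_equal(sort(stratum_causal_rrs(pop)$rr_c), c(1.5, 3))
})

test_that("degenerate and null-effect populations behave as expected", {
  single <- stratified_population(tibble::tibble(
    stratum = "only", exposure = 0L, proportion = 1, risk = 0.37
  ))
  expect_equal(observed_risk(single), 0.37)
  expect_equal(counterfactual_risk(single), 0.37)
  expect_equal(paf_definition(single)$estimate, 0)
  expect_equal(exposure_prevalence(single), 0)
  expect_equal(case_prevalence(single), 0)

  null_pop <- null_effect_pop()
  expect_equal(paf_definition(null_pop)$estimate, 0)
  expect_equal(marginal_causal_rr(null_pop), 1)
  expect_equal(causal_rr_exposed(null_pop), 1)
  expect_equal(paf_effect_modification(null_pop)$estimate, 0)
})

test_that("counterfactual standardization checks the target level per stratum", {
  pop <- stratified_population(tibble::tibble(
    stratum = c("a", "a", "b"),
    exposure = c(0L, 2L, 0L),
    proportion = c(0.3, 0.3, 0.4),
    risk = c(0.1, 0.3, 0.2)
  ))
  # a stratum missing a non-reference level contributes no exposed mass
  expect_equal(exposure_prevalence(pop), 0.3)
  expect_error(counterfactual_risk(pop, 2L),
               class = "pafbias_error_missing_reference", regexp = "b")
  expect_error(marginal_causal_rr(pop, 2L),
               class = "pafbias_error_missing_reference")
  # setting everyone to the level they already have reproduces observation
  all_ref <- stratified_population(tibble::tibble(
    stratum = c("a", "b"), exposure = c(0L, 0L),
    proportion = c(0.6, 0.4), risk = c(0.05, 0.2)
  ))
  expect_equal(counterfactual_risk(all_ref, 0L), observed_risk(all_ref))
})

test_that("binary-only summaries reject multi-level populations", {
  pop <- stratified_population(tibble::tibble(
    stratum = c("a", "a", "a"),
    exposure = c(0L, 1L, 2L),
    proportion = c(0.5, 0.3, 0.2),
    risk = c(0.1, 0.15, 0.3)
  ))
  expect_error(case_prevalence(pop), class = "pafbias_error_non_binary")
  expect_error(causal_rr_exposed(pop), class = "pafbias_error_non_binary")
  # but the general effect-modification decomposition still matches Eq 1
  expect_equal(paf_effect_modification(pop)$estimate,
               paf_definition(pop)$estimate, tolerance = 1e-14)
  expect_identical(paf_effect_modification(pop)$formula, "eq_general_em")
})

test_that("case-weighted decomposition and exposed-RR identity hold on the fixtures", {
  for (pop in list(table1_pop(), table1_em_pop())) {
    truth <- paf_definition(pop)$estimate
    expect_equal(paf_effect_modification(pop)$estimate, truth, tolerance = 1e-13)
    # Miettinen's exposed-RR identity survives effect modification
    expect_equal(
      case_prevalence(pop) * (causal_rr_exposed(pop) - 1) / causal_rr_exposed(pop),
      truth,
      tolerance = 1e-13
    )
  }
})

test_that("population_summaries gathers all quantities in one row", {
  s <- population_summaries(table1_em_pop())
  expect_s3_class(s, "tbl_df")
  expect_equal(nrow(s), 1L)
  expect_equal(s$paf, 5 / 13)
  expect_equal(s$rr_e, 2.25)
  expect_equal(nrow(s$stratum_rrs[[1]]), 2L)
})
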
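# parameterised property suites, shared between the unit tests (small n)
# and the full randomized suites (n = 200). Each returns the worst-case
# error(s) or a logical summary over n random cases under a fixed seed.

# effect-modification decomposition equals the counterfactual definition
prop_em_identity <- function(n, seed) {
  set.seed(seed)
  max(vapply(seq_len(n), function(i) {
    pop <- random_pop(effect_modification = TRUE)
    abs(paf_effect_modification(pop)$estimate - paf_definition(pop)$estimate)
  }, numeric(1)))
}

# under constant stratum RR both Miettinen forms equal the definition
prop_constant_rr <- function(n, seed) {
  set.seed(seed)
  errs <- t(vapply(seq_len(n), function(i) {
    pop <- random_pop(effect_modification = FALSE)
    truth <- paf_definition(pop)$estimate
    eq3 <- paf_miettinen_pc(case_prevalence(pop), marginal_causal_rr(pop))$estimate
    eq4 <- paf_miettinen_three(exposure_prevalence(pop), unadjusted_rr(pop),
                               marginal_causal_rr(pop))$estimate
    c(eq3 = abs(eq3 - truth), eq4 = abs(eq4 - truth))
  }, c(eq3 = 0, eq4 = 0)))
  apply(errs, 2, max)
}

# exposure independent of the confounder: crude RR equals the marginal
# causal RR and Levin's formula is exact (even under effect modification)
prop_no_confounding <- function(n, seed) {
  set.seed(seed)
  errs <- t(vapply(seq_len(n), function(i) {
    spec <- random_population_spec(sample(1:4, 1),
                                   effect_modification = sample(c(TRUE, FALSE), 1))
    spec$exposure_prevalence_by_stratum <-
      rep(runif(1, 0.05, 0.95), spec$n_strata)
    pop <- make_population(spec)
    c(
      rr = abs(unadjusted_rr(pop) - marginal_causal_rr(pop)),
      levin = abs(paf_levin(exposure_prevalence(pop), marginal_causal_rr(pop))$estimate -
                    paf_definition(pop)$estimate)
    )
  }, c(rr = 0, levin = 0)))
  apply(errs, 2, max)
}

# relative bias strictly increasing in C; worse (farther from 1) for
# smaller prevalence at any fixed C != 1
prop_bias_monotone <- function(n, seed) {
  set.seed(seed)
  all(vapply(seq_len(n), function(i) {
    pi_big <- runif(1, 0.1, 0.99)
    pi_small <- runif(1, 0.01, pi_big)
    rr_u <- runif(1, 0.3, 4)
    cs <- sort(exp(runif(6, log(0.05), log(20))))
    rb <- relative_bias(pi_big, rr_u, cs)
    increasing <- all(diff(rb) > 0)
    cs_off <- cs[abs(cs - 1) > 1e-6]
    worse_small_pi <- all(
      abs(relative_bias(pi_small, rr_u, cs_off) - 1) >=
        abs(relative_bias(pi_big, rr_u, cs_off) - 1) - 1e-12
    )
    increasing && worse_small_pi
  }, logical(1)))
}

# unadjusted Levin flips sign when RR_U and RR_C straddle 1; causal-RR
# Levin keeps the sign of the true effect
prop_sign_flip <- function(n, seed) {
  set.seed(seed)
  all(vapply(seq_len(n), function(i) {
    pi <- runif(1, 0.05, 0.95)
    # harmful exposure masked by confounding: RR_U < 1 < RR_C
    rr_u1 <- runif(1, 0.3, 0.99)
    rr_c1 <- runif(1, 1.01, 4)
    harmful <- paf_levin(pi, rr_u1, rr_type = "unadjusted")$estimate < 0 &&
      paf_miettinen_three(pi, rr_u1, rr_c1)$estimate > 0 &&
      paf_levin(pi, rr_c1)$estimate > 0
    # protective exposure made to look harmful: RR_U > 1 > RR_C
    rr_u2 <- runif(1, 1.01, 4)
    rr_c2 <- runif(1, 0.3, 0.99)
    protective <- paf_levin(pi, rr_u2, rr_type = "unadjusted")$estimate > 0 &&
      paf_miettinen_three(pi, rr_u2, rr_c2)$estimate < 0
    harmful && protective
  }, logical(1)))
}

# random multicategory profile with rr_u; binary collapse and the Bayes
# equivalence between the case-density and three-variable general forms
random_profile <- function(n_levels) {
  mass <- rgamma(n_levels, 1)
  mass <- mass / sum(mass)
  rr_c <- c(1, runif(n_levels - 1, 0.3, 4))
  rr_u <- c(1, runif(n_levels - 1, 0.3, 4))
  exposure_profile(
    tibble::tibble(x = seq_len(n_levels) - 1L, density = mass,
                   rr_c = rr_c, rr_u = rr_u),
    kind = "multicategory"
  )
}

prop_general_exposure <- function(n, seed) {
  set.seed(seed)
  errs <- t(vapply(seq_len(n), function(i) {
    two <- random_profile(2L)
    pi1 <- two$density[two$x == 1L]
    collapse <- max(
      abs(paf_levin_general(two)$estimate -
            paf_levin(pi1, two$rr_c[two$x == 1L])$estimate),
      abs(paf_miettinen_general(two)$estimate -
            paf_miettinen_three(pi1, two$rr_u[two$x == 1L],
                                two$rr_c[two$x == 1L])$estimate)
    )
    multi <- random_profile(sample(3:6, 1))
    bayes <- abs(paf_miettinen_cases(case_profile(multi))$estimate -
                   paf_miettinen_general(multi)$estimate)
    c(collapse = collapse, bayes = bayes)
  }, c(collapse = 0, bayes = 0)))
  apply(errs, 2, max)
}
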
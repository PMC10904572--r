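test_that("profile construction validates grid, masses and reference RRs", {
  ok <- exposure_profile(
    tibble::tibble(x = 0:2, density = c(0.5, 0.3, 0.2), rr_c = c(1, 2, 4)),
    kind = "multicategory"
  )
  expect_s3_class(ok, "exposure_profile")

  expect_error(
    exposure_profile(tibble::tibble(x = 0:1, density = c(0.5, 0.4), rr_c = c(1, 2)),
                     kind = "multicategory"),
    class = "pafbias_error_invalid_profile"
  )
  expect_error(
    exposure_profile(tibble::tibble(x = 0:1, density = c(0.5, 0.5), rr_c = c(1.2, 2)),
                     kind = "multicategory"),
    class = "pafbias_error_invalid_profile"
  )
  expect_error(
    exposure_profile(tibble::tibble(x = 1:2, density = c(0.5, 0.5), rr_c = c(1, 2)),
                     kind = "multicategory"),
    class = "pafbias_error_invalid_profile"
  )
  # continuous density off by more than 1e-3 renormalizes with a warning
  expect_warning(
    exposure_profile(
      tibble::tibble(x = seq(0, 1, 0.1), density = rep(2, 11),
                     rr_c = rep(1, 11)),
      kind = "continuous"
    ),
    class = "pafbias_warning_density_renormalized"
  )
  # abrupt RR jumps on a continuous grid trigger the coarse-grid warning
  expect_warning(
    exposure_profile(
      tibble::tibble(x = c(0, 1, 2), density = c(0.5, 0.5, 0.5),
                     rr_c = c(1, 2, 1)),
      kind = "continuous"
    ),
    class = "pafbias_warning_coarse_grid"
  )
})

test_that("generalised Levin matches weighted-sum oracles and binary collapse", {
  # brute-force oracle for a 3-level profile
  prof3 <- exposure_profile(
    tibble::tibble(x = 0:2, density = c(0.5, 0.3, 0.2), rr_c = c(1, 2, 4)),
    kind = "multicategory"
  )
  e_rr <- 0.5 * 1 + 0.3 * 2 + 0.2 * 4
  expect_equal(paf_levin_general(prof3)$estimate, (e_rr - 1) / e_rr)

  binary <- exposure_profile(
    tibble::tibble(x = 0:1, density = c(0.55, 0.45), rr_c = c(1, 1.5)),
    kind = "multicategory"
  )
  expect_equal(paf_levin_general(binary)$estimate,
               paf_levin(0.45, 1.5)$estimate, tolerance = 1e-15)

  flat <- exposure_profile(
    tibble::tibble(x = 0:3, density = rep(0.25, 4), rr_c = rep(1, 4)),
    kind = "multicategory"
  )
  expect_equal(paf_levin_general(flat)$estimate, 0)
})

test_that("generalised Miettinen collapses to the binary formulas and needs RR_U", {
  binary <- exposure_profile(
    tibble::tibble(x = 0:1, density = c(0.55, 0.45),
                   rr_c = c(1, 1.5), rr_u = c(1, 11 / 6)),
    kind = "multicategory"
  )
  expect_equal(paf_miettinen_general(binary)$estimate, 0.2, tolerance = 1e-15)

  no_rru <- exposure_profile(
    tibble::tibble(x = 0:1, density = c(0.55, 0.45), rr_c = c(1, 1.5)),
    kind = "multicategory"
  )
  expect_error(paf_miettinen_general(no_rru), class = "pafbias_error_missing_rr_u")

  # no confounding: the two general estimators agree
  set.seed(21)
  for (i in 1:25) {
    prof <- random_profile(sample(2:6, 1))
    prof$rr_u <- prof$rr_c
    expect_equal(paf_miettinen_general(prof)$estimate,
                 paf_levin_general(prof)$estimate, tolerance = 1e-13)
  }
})

test_that("case-density form reduces to the case-prevalence formula for binary exposure", {
  case_binary <- exposure_profile(
    tibble::tibble(x = 0:1, density = c(0.4, 0.6), rr_c = c(1, 1.5)),
    kind = "multicategory"
  )
  expect_equal(paf_miettinen_cases(case_binary)$estimate, 0.2, tolerance = 1e-15)
  flat_rr <- exposure_profile(
    tibble::tibble(x = 0:2, density = c(0.2, 0.5, 0.3), rr_c = c(1, 1, 1)),
    kind = "multicategory"
  )
  expect_equal(paf_miettinen_cases(flat_rr)$estimate, 0)
})

test_that("case-density and population-density forms agree through Bayes' rule", {
  prof <- make_continuous_profile(n_grid = 301, log_rr_slope = 0.25,
                                  log_confounding_slope = 0.08)
  expect_equal(paf_miettinen_cases(case_profile(prof))$estimate,
               paf_miettinen_general(prof)$estimate, tolerance = 1e-12)
})

test_that("trapezoid quadrature is converged on smooth profiles", {
  est <- function(n) {
    prof <- make_continuous_profile(n_grid = n, x_max = 6, sdlog = 0.5,
                                    log_rr_slope = 0.3,
                                    log_confounding_slope = 0.1)
    c(paf_levin_general(prof)$estimate, paf_miettinen_general(prof)$estimate)
  }
  coarse <- est(801)
  fine <- est(1601)
  expect_lt(max(abs(coarse - fine)), 1e-6)
})

test_that("a discretized profile agrees with the stratified-population oracle", {
  prof <- make_continuous_profile(n_grid = 161, x_max = 4, log_rr_slope = 0.35,
                                  log_confounding_slope = 0)
  # trapezoid weights turn the gridded density into exact cell masses
  n <- nrow(prof)
  dx <- diff(prof$x)
  w <- c(dx[1] / 2, (dx[-1] + dx[-(n - 1)]) / 2, dx[n - 1] / 2) * prof$density
  w <- w / sum(w)
  pop <- stratified_population(tibble::tibble(
    stratum = "all",
    exposure = seq_len(n) - 1L,
    proportion = w,
    risk = 0.02 * prof$rr_c
  ))
  truth <- paf_definition(pop)$estimate
  # same quadrature measure, so the unconfounded estimators match exactly
  disc <- exposure_profile(
    tibble::tibble(x = seq_len(n) - 1L, density = w,
                   rr_c = prof$rr_c, rr_u = prof$rr_c),
    kind = "multicategory"
  )
  expect_equal(paf_levin_general(disc)$estimate, truth, tolerance = 1e-12)
  expect_equal(paf_miettinen_general(disc)$estimate, truth, tolerance = 1e-12)
})

test_that("point mass at the reference value gives zero PAF for every formula", {
  prof <- exposure_profile(
    tibble::tibble(x = 0:1, density = c(1, 0), rr_c = c(1, 2), rr_u = c(1, 3)),
    kind = "multicategory"
  )
  expect_equal(paf_levin_general(prof)$estimate, 0)
  expect_equal(paf_miettinen_general(prof)$estimate, 0)
  expect_equal(paf_miettinen_cases(prof)$estimate, 0)
})
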
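#' Construct a confounder-stratified population
#'
#' A stratified population is the ground-truth object of the package: a full
#' joint table of confounder stratum by exposure level, carrying the fraction
#' of the population in each cell and the probability of disease in that cell.
#' Every summary-data PAF formula in the package can be checked against
#' quantities computed directly from such a table.
#'
#' @param data A data frame with columns `stratum` (confounder stratum label),
#'   `exposure` (non-negative integer exposure code; 0 is the reference /
#'   minimum-risk level), `proportion` (fraction of the total population in the
#'   cell) and `risk` (probability of disease in the cell).
#' @param normalize If `TRUE`, proportions are rescaled to sum to one. By
#'   default construction fails when proportions do not sum to one within
#'   `tol`, because silent renormalization hides data-entry errors.
#' @param tol Tolerance for the sum-to-one check.
#'
#' @return A tibble of class `stratified_population`, one row per
#'   (stratum, exposure) cell, sorted by stratum then exposure.
#'
#' @details Each stratum must contain a cell at exposure 0: without a
#'   reference cell the counterfactual risk of the stratum is undefined. A
#'   stratum may lack non-reference levels; it then simply contributes no
#'   exposed mass.
#'
#' @examples
#' pop <- stratified_population(data.frame(
#'   stratum    = c("high", "high", "low", "low"),
#'   exposure   = c(0L, 1L, 0L, 1L),
#'   proportion = c(0.5, 0.3, 0.05, 0.15),
#'   risk       = c(0.1, 0.15, 0.2, 0.3)
#' ))
#' observed_risk(pop)
#' tidy(paf_definition(pop))
#' @export
stratified_population <- function(data, normalize = FALSE, tol = 1e-9) {
  if (!is.data.frame(data)) {
    paf_abort("`data` must be a data frame.", "pafbias_error_invalid_population")
  }
  required <- c("stratum", "exposure", "proportion", "risk")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    paf_abort(
      sprintf("`data` is missing required column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "pafbias_error_invalid_population"
    )
  }
  x <- as_tibble(data)[required]
  x$stratum <- as.character(x$stratum)
  if (!is.numeric(x$exposure) || anyNA(x$exposure) ||
      any(x$exposure < 0) || any(x$exposure != round(x$exposure))) {
    paf_abort("`exposure` must contain non-negative integer codes (0 = reference).",
              "pafbias_error_invalid_population")
  }
  x$exposure <- as.integer(round(x$exposure))
  check_prob(x$proportion, "proportion")
  check_prob(x$risk, "risk")

  total <- sum(x$proportion)
  if (abs(total - 1) > tol) {
    if (normalize) {
      x$proportion <- x$proportion / total
    } else {
      paf_abort(
        sprintf("Cell proportions sum to %.12g, not 1 (tolerance %g). Use `normalize = TRUE` to rescale deliberately.",
                total, tol),
        "pafbias_error_invalid_population"
      )
    }
  }

  dup <- duplicated(x[c("stratum", "exposure")])
  if (any(dup)) {
    bad <- x[dup, ]
    paf_abort(
      sprintf("Duplicate (stratum, exposure) cell(s): %s.",
              paste(sprintf("(%s, %d)", bad$stratum, bad$exposure), collapse = "; ")),
      "pafbias_error_invalid_population"
    )
  }

  no_ref <- setdiff(unique(x$stratum), x$stratum[x$exposure == 0L])
  if (length(no_ref)) {
    paf_abort(
      sprintf("Stratum(s) without a reference (exposure 0) cell: %s. The counterfactual risk is undefined there.",
              paste(no_ref, collapse = ", ")),
      "pafbias_error_missing_reference"
    )
  }

  x <- arrange(x, .data$stratum, .data$exposure)
  class(x) <- c("stratified_population", class(tibble()))
  x
}

is_stratified_population <- function(x) inherits(x, "stratified_population")

assert_population <- function(pop) {
  if (!is_stratified_population(pop)) {
    pop <- stratified_population(pop)
  }
  pop
}

#' Exposure levels present in a population
#' @param pop A [stratified_population()].
#' @return Sorted integer vector of distinct exposure codes.
#' @export
exposure_levels <- function(pop) {
  pop <- assert_population(pop)
  sort(unique(pop$exposure))
}

is_binary_population <- function(pop) {
  all(exposure_levels(pop) %in% c(0L, 1L))
}

assert_binary <- function(pop, what) {
  if (!is_binary_population(pop)) {
    paf_abort(
      sprintf("%s is defined for binary exposures only; this population has levels %s.",
              what, paste(exposure_levels(pop), collapse = ", ")),
      "pafbias_error_non_binary"
    )
  }
  invisible(pop)
}

# risk of each stratum at a given exposure level, as a named vector
stratum_risk_at <- function(pop, level, what) {
  cells <- pop[pop$exposure == level, ]
  missing <- setdiff(unique(pop$stratum), cells$stratum)
  if (length(missing)) {
    paf_abort(
      sprintf("%s requires a cell at exposure level %d in every stratum; missing in stratum(s): %s.",
              what, level, paste(missing, collapse = ", ")),
      "pafbias_error_missing_reference"
    )
  }
  setNames(cells$risk, cells$stratum)
}

#' Observed disease risk of a stratified population
#'
#' The marginal disease prevalence \eqn{P(Y=1)}: a proportion-weighted
#' average of the cell risks.
#'
#' @inheritParams exposure_levels
#' @return A probability.
#' @export
observed_risk <- function(pop) {
  pop <- assert_population(pop)
  sum(pop$proportion * pop$risk)
}

#' Counterfactual disease risk under a uniform exposure intervention
#'
#' The disease prevalence \eqn{P(Y_{x}=1)} that would be observed had every
#' individual been set to `target_level`, computed by conditional-
#' exchangeability standardization: each cell keeps its population share but
#' takes the risk of the cell in the same confounder stratum at
#' `target_level`.
#'
#' @inheritParams exposure_levels
#' @param target_level Exposure code to set everyone to (default 0, the
#'   reference / minimum-risk exposure value).
#' @return A probability.
#' @export
counterfactual_risk <- function(pop, target_level = 0L) {
  pop <- assert_population(pop)
  ref <- stratum_risk_at(pop, target_level, "counterfactual_risk()")
  sum(pop$proportion * ref[pop$stratum])
}

#' PAF from its counterfactual definition
#'
#' The population attributable fraction
#' \deqn{PAF = \frac{P(Y=1) - P(Y_0=1)}{P(Y=1)},}
#' the fraction of prevalent cases that would be avoided were everyone set to
#' the reference exposure. This is the oracle the summary-data formulas are
#' judged against. The value may be negative for a protective exposure and is
#' returned unclamped.
#'
#' @inheritParams counterfactual_risk
#' @return A [paf_result] with formula tag `"definition"`.
#' @export
paf_definition <- function(pop, target_level = 0L) {
  pop <- assert_population(pop)
  obs <- observed_risk(pop)
  if (obs <= 0) {
    paf_abort("PAF is undefined when the observed risk P(Y=1) is 0.",
              "pafbias_error_domain")
  }
  cf <- counterfactual_risk(pop, target_level)
  paf_result((obs - cf) / obs, "definition",
             list(observed_risk = obs, counterfactual_risk = cf,
                  target_level = as.integer(target_level)))
}

#' Marginal causal relative risk
#'
#' The ratio of counterfactual prevalences comparing the scenario where the
#' entire population is set to exposure `level` against the scenario where it
#' is set to the reference: \eqn{RR_C = P(Y_{level}=1)/P(Y_0=1)}. Both
#' counterfactual risks standardize the stratum-specific risks over the
#' population's confounder distribution.
#'
#' @inheritParams exposure_levels
#' @param level Exposure code for the numerator scenario (default 1).
#' @return A ratio.
#' @export
marginal_causal_rr <- function(pop, level = 1L) {
  pop <- assert_population(pop)
  num <- counterfactual_risk(pop, level)
  den <- counterfactual_risk(pop, 0L)
  if (den <= 0) {
    paf_abort("Marginal causal RR undefined: counterfactual reference risk is 0.",
              "pafbias_error_domain")
  }
  num / den
}

#' Causal relative risk among the exposed
#'
#' For a binary exposure, \eqn{RR_e = P(Y_1=1 \mid X=1)/P(Y_0=1 \mid X=1)}:
#' stratum-specific risks standardized over the confounder distribution of
#' the exposed subpopulation. Under effect modification this is the relative
#' risk that makes Miettinen's case-prevalence formula exact.
#'
#' @inheritParams exposure_levels
#' @return A ratio.
#' @export
causal_rr_exposed <- function(pop) {
  pop <- assert_population(pop)
  assert_binary(pop, "causal_rr_exposed()")
  exp_cells <- pop[pop$exposure == 1L, ]
  if (nrow(exp_cells) == 0L || sum(exp_cells$proportion) <= 0) {
    paf_abort("causal_rr_exposed() requires exposed mass in the population.",
              "pafbias_error_domain")
  }
  r1 <- stratum_risk_at(pop, 1L, "causal_rr_exposed()")
  r0 <- stratum_risk_at(pop, 0L, "causal_rr_exposed()")
  w <- exp_cells$proportion / sum(exp_cells$proportion)
  num <- sum(w * r1[exp_cells$stratum])
  den <- sum(w * r0[exp_cells$stratum])
  if (den <= 0) {
    paf_abort("Causal RR among the exposed undefined: reference risk is 0 among the exposed.",
              "pafbias_error_domain")
  }
  num / den
}

#' Unadjusted (crude) relative risk
#'
#' The observed risk ratio \eqn{RR_U = P(Y=1 \mid X=level)/P(Y=1 \mid X=0)},
#' each conditional risk being the proportion-weighted average of cell risks
#' within the exposure group. Confounding is deliberately left in; the gap
#' between `unadjusted_rr()` and [marginal_causal_rr()] is what drives the
#' bias of Levin's formula.
#'
#' @inheritParams marginal_causal_rr
#' @return A ratio.
#' @export
unadjusted_rr <- function(pop, level = 1L) {
  pop <- assert_population(pop)
  grp <- function(lv) {
    cells <- pop[pop$exposure == lv, ]
    if (nrow(cells) == 0L || sum(cells$proportion) <= 0) {
      paf_abort(
        sprintf("unadjusted_rr(): no population mass at exposure level %d.", lv),
        "pafbias_error_domain"
      )
    }
    sum(cells$proportion * cells$risk) / sum(cells$proportion)
  }
  den <- grp(0L)
  if (den <= 0) {
    paf_abort("Unadjusted RR undefined: observed risk in the reference group is 0.",
              "pafbias_error_domain")
  }
  grp(level) / den
}

#' Exposure prevalence and case prevalence of exposure
#'
#' `exposure_prevalence()` returns \eqn{\pi = P(X \neq 0)}, the fraction of
#' the population at any non-reference exposure level. `case_prevalence()`
#' returns \eqn{\pi_c = P(X=1 \mid Y=1)}, the fraction of disease cases that
#' are exposed (binary exposures only) — the quantity Miettinen's
#' case-prevalence formula consumes.
#'
#' @inheritParams exposure_levels
#' @return A probability.
#' @export
exposure_prevalence <- function(pop) {
  pop <- assert_population(pop)
  sum(pop$proportion[pop$exposure != 0L])
}

#' @rdname exposure_prevalence
#' @export
case_prevalence <- function(pop) {
  pop <- assert_population(pop)
  assert_binary(pop, "case_prevalence()")
  obs <- observed_risk(pop)
  exp_cases <- sum(pop$proportion[pop$exposure == 1L] * pop$risk[pop$exposure == 1L])
  if (obs <= 0) {
    if (exp_cases == 0) return(0)
    paf_abort("Case prevalence undefined: observed risk P(Y=1) is 0.",
              "pafbias_error_domain")
  }
  exp_cases / obs
}

#' Per-stratum causal relative risks
#'
#' The causal relative risk within each confounder stratum,
#' \eqn{RR_C(c) = P(Y_{level}=1 \mid C=c)/P(Y_0=1 \mid C=c)}. Variation across
#' strata is effect modification on the relative-risk scale.
#'
#' @inheritParams marginal_causal_rr
#' @return A tibble with columns `stratum` and `rr_c`.
#' @export
stratum_causal_rrs <- function(pop, level = 1L) {
  pop <- assert_population(pop)
  r1 <- stratum_risk_at(pop, level, "stratum_causal_rrs()")
  r0 <- stratum_risk_at(pop, 0L, "stratum_causal_rrs()")
  strata <- sort(names(r0))
  tibble(stratum = strata, rr_c = unname(r1[strata] / r0[strata]))
}

#' PAF allowing effect modification across confounder strata
#'
#' Computes the PAF as a case-weighted expectation over confounder strata.
#' For a binary exposure it averages, over the confounder distribution among
#' cases, the exposed-case fraction of the stratum times
#' \eqn{(RR_C(c)-1)/RR_C(c)} with \eqn{RR_C(c)} the stratum-specific causal
#' relative risk. For multi-level exposures it takes the double expectation
#' over (stratum, exposure) among cases of \eqn{(RR_C(x,c)-1)/RR_C(x,c)}.
#' Both forms are exact identities for the counterfactual definition, with no
#' constant-relative-risk assumption, so the result equals [paf_definition()]
#' up to floating-point error.
#'
#' @inheritParams exposure_levels
#' @return A [paf_result] with formula tag `"eq_binary_em"` for binary
#'   exposures or `"eq_general_em"` otherwise.
#' @export
paf_effect_modification <- function(pop) {
  pop <- assert_population(pop)
  obs <- observed_risk(pop)
  if (obs <= 0) {
    paf_abort("PAF is undefined when the observed risk P(Y=1) is 0.",
              "pafbias_error_domain")
  }
  r0 <- stratum_risk_at(pop, 0L, "paf_effect_modification()")
  cells <- pop[pop$exposure != 0L, ]
  # joint density of (stratum, exposure) among cases
  p_case <- cells$proportion * cells$risk / obs
  # (RR-1)/RR written as 1 - 1/RR so that an infinite stratum RR (reference
  # risk 0) contributes its full case mass instead of NaN
  inv_rr <- ifelse(cells$risk > 0, r0[cells$stratum] / cells$risk, NA_real_)
  term <- ifelse(p_case > 0, p_case * (1 - inv_rr), 0)
  tag <- if (is_binary_population(pop)) "eq_binary_em" else "eq_general_em"
  paf_result(sum(term), tag, list(observed_risk = obs))
}
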
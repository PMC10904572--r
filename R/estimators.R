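#' Levin's attributable-fraction formula
#'
#' \deqn{PAF_L = \frac{\pi (RR - 1)}{1 + \pi (RR - 1)}}
#' where \eqn{\pi} is the exposure prevalence in the population. The formula
#' identifies the true PAF only when the relative risk supplied is causal
#' *and* exposure is unconfounded (no confounding in risk ratio, no effect
#' modification); otherwise it is biased — see [relative_bias()].
#'
#' The caller chooses whether `rr` is a causal or an unadjusted relative
#' risk; the package cannot verify causality, so the choice is only recorded
#' as a provenance tag in the result.
#'
#' @param pi Exposure prevalence in `[0, 1]`.
#' @param rr Relative risk (> 0).
#' @param rr_type `"causal"` (tag `levin`) or `"unadjusted"` (tag
#'   `levin_unadjusted`).
#' @return A [paf_result].
#' @examples
#' tidy(paf_levin(0.45, 1.5))  # 0.1837, the classic underestimate of 0.2
#' @export
paf_levin <- function(pi, rr, rr_type = c("causal", "unadjusted")) {
  rr_type <- match.arg(rr_type)
  check_prob(pi, "pi")
  check_positive(rr, "rr")
  est <- pi * (rr - 1) / (1 + pi * (rr - 1))
  paf_result(est, if (rr_type == "causal") "levin" else "levin_unadjusted",
             list(pi = pi, rr = rr, rr_type = rr_type))
}

#' Miettinen's case-prevalence formula
#'
#' \deqn{PAF_M = \pi_c \frac{RR_C - 1}{RR_C}}
#' where \eqn{\pi_c} is the prevalence of exposure among disease cases. Exact
#' under confounding provided the causal relative risk is constant across
#' confounder strata; under effect modification it remains exact when the
#' causal RR among the exposed ([causal_rr_exposed()]) is supplied.
#'
#' @param pi_c Exposure prevalence among cases, in `[0, 1]`.
#' @param rr_c Causal relative risk (> 0).
#' @return A [paf_result].
#' @examples
#' tidy(paf_miettinen_pc(0.6, 1.5))  # exactly 0.2
#' @export
paf_miettinen_pc <- function(pi_c, rr_c) {
  check_prob(pi_c, "pi_c")
  check_positive(rr_c, "rr_c")
  paf_result(pi_c * (rr_c - 1) / rr_c, "miettinen_pc",
             list(pi_c = pi_c, rr_c = rr_c))
}

#' Miettinen's three-variable formula
#'
#' \deqn{PAF_M = \left[\frac{\pi RR_U}{1 + \pi(RR_U - 1)}\right]
#'   \frac{RR_C - 1}{RR_C}}
#' The bracketed term is \eqn{\pi_c} recovered from the population prevalence
#' \eqn{\pi} and the unadjusted relative risk \eqn{RR_U} by Bayes' rule —
#' convenient because unadjusted relative risks are reported in the
#' literature far more often than case prevalences. When `rr_u == rr_c`
#' (no confounding in risk ratio) the expression collapses to Levin's
#' formula.
#'
#' @param pi Exposure prevalence in `[0, 1]`.
#' @param rr_u Unadjusted relative risk (> 0).
#' @param rr_c Causal relative risk (> 0).
#' @param pi_c Optional explicit case prevalence. When supplied it replaces
#'   the Bayes-derived bracketed term; if it disagrees with the derived value
#'   by more than `1e-6` (commonly because published inputs were rounded) a
#'   warning is emitted and the explicit value is used.
#' @return A [paf_result].
#' @examples
#' tidy(paf_miettinen_three(0.45, 11/6, 1.5))  # exactly 0.2
#' @export
paf_miettinen_three <- function(pi, rr_u, rr_c, pi_c = NULL) {
  check_prob(pi, "pi")
  check_positive(rr_u, "rr_u")
  check_positive(rr_c, "rr_c")
  pi_c_derived <- pi * rr_u / (1 + pi * (rr_u - 1))
  if (!is.null(pi_c)) {
    check_prob(pi_c, "pi_c")
    if (abs(pi_c - pi_c_derived) > 1e-6) {
      warn(sprintf(
        "Supplied pi_c = %.8g differs from the value %.8g implied by (pi, rr_u); proceeding with the supplied value (rounded published inputs?).",
        pi_c, pi_c_derived
      ), class = "pafbias_warning_inconsistent_pi_c")
    }
    bracket <- pi_c
  } else {
    bracket <- pi_c_derived
  }
  paf_result(bracket * (rr_c - 1) / rr_c, "miettinen_three",
             list(pi = pi, rr_u = rr_u, rr_c = rr_c, pi_c = bracket))
}
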
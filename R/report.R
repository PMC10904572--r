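#' Worked-example report
#'
#' Recomputes, end to end from the packaged fixtures, the two textbook
#' demonstrations of Levin-formula bias: the constant-relative-risk
#' population (`table1.csv`, where Miettinen's formulas recover the true PAF
#' of 0.2 while Levin's gives 0.184) and its effect-modification variant
#' (`table1_em.csv`, where plugging the marginal causal RR into the
#' three-variable formula gives 0.346 against a true PAF of 0.385, and only
#' the causal RR among the exposed restores exactness).
#'
#' @param format `"markdown"` for a human-readable table (values rounded to
#'   3 significant figures alongside full precision) or `"json"` for
#'   machine-readable full-precision output.
#' @return A character vector of report lines, invisibly printable with
#'   `cat(..., sep = "\n")`. The output is deterministic: regeneration is
#'   byte-identical.
#' @export
run_worked_example <- function(format = c("markdown", "json")) {
  format <- match.arg(format)
  pops <- list(
    table1 = read_population_csv(pafbias_example("table1.csv")),
    table1_em = read_population_csv(pafbias_example("table1_em.csv"))
  )
  quantify <- function(pop) {
    s <- population_summaries(pop)
    list(
      observed_risk = s$observed_risk,
      counterfactual_risk = s$counterfactual_risk,
      paf = s$paf,
      pi = s$pi,
      pi_c = s$pi_c,
      rr_u = s$rr_u,
      rr_c_marginal = s$rr_c_marginal,
      rr_e = s$rr_e,
      levin_rr_c = paf_levin(s$pi, s$rr_c_marginal)$estimate,
      miettinen_pi_c_rr_e = paf_miettinen_pc(s$pi_c, s$rr_e)$estimate,
      miettinen_three_marginal =
        paf_miettinen_three(s$pi, s$rr_u, s$rr_c_marginal)$estimate,
      paf_effect_modification = paf_effect_modification(pop)$estimate
    )
  }
  vals <- lapply(pops, quantify)

  if (format == "json") {
    payload <- lapply(vals, function(v) {
      c(v, list(rounded = lapply(v, signif, digits = 3)))
    })
    return(strsplit(as.character(
      jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ), "\n", fixed = TRUE)[[1]])
  }

  qty <- names(vals$table1)
  fmt <- function(x) sprintf("%.10g", x)
  rows <- vapply(qty, function(q) {
    sprintf("| %s | %s | %s | %s | %s |",
            q,
            fmt(vals$table1[[q]]), fmt(signif(vals$table1[[q]], 3)),
            fmt(vals$table1_em[[q]]), fmt(signif(vals$table1_em[[q]], 3)))
  }, character(1))
  c(
    "# Worked example: Levin vs Miettinen under confounding",
    "",
    "| quantity | constant-RR population | (3 s.f.) | effect-modification variant | (3 s.f.) |",
    "|---|---|---|---|---|",
    unname(rows),
    "",
    "The definition PAF is the oracle; `levin_rr_c` shows Levin's bias under",
    "confounding, `miettinen_three_marginal` shows the residual bias of the",
    "three-variable formula when the marginal causal RR is used despite",
    "effect modification, and `miettinen_pi_c_rr_e` (case prevalence with the",
    "causal RR among the exposed) is exact in both populations."
  )
}
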
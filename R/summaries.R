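#' Summarise a stratified population
#'
#' Computes, in one pass, every summary a PAF analysis from aggregate data
#' would need: the observed and counterfactual risks, the definition PAF, the
#' exposure prevalence \eqn{\pi} and case prevalence \eqn{\pi_c}, the
#' unadjusted relative risk \eqn{RR_U}, the marginal causal relative risk
#' \eqn{RR_C}, the causal relative risk among the exposed \eqn{RR_e}, and
#' the per-stratum causal relative risks. The binary-only quantities
#' (\eqn{\pi_c}, \eqn{RR_e}) are `NA` for multi-level exposures.
#'
#' @param pop A [stratified_population()].
#' @param level Non-reference exposure level used for the relative-risk
#'   summaries (default 1).
#' @return A one-row tibble with the columns above; the per-stratum RRs live
#'   in the `stratum_rrs` list-column.
#' @examples
#' pop <- read_population_csv(pafbias_example("table1.csv"))
#' population_summaries(pop)
#' @export
population_summaries <- function(pop, level = 1L) {
  pop <- assert_population(pop)
  binary <- is_binary_population(pop)
  obs <- observed_risk(pop)
  cf <- counterfactual_risk(pop, 0L)
  tibble(
    observed_risk = obs,
    counterfactual_risk = cf,
    paf = paf_definition(pop)$estimate,
    pi = exposure_prevalence(pop),
    pi_c = if (binary) case_prevalence(pop) else NA_real_,
    rr_u = unadjusted_rr(pop, level),
    rr_c_marginal = marginal_causal_rr(pop, level),
    rr_e = if (binary && exposure_prevalence(pop) > 0) causal_rr_exposed(pop) else NA_real_,
    stratum_rrs = list(stratum_causal_rrs(pop, level))
  )
}

#' Serialize population summaries to JSON
#'
#' Writes the full-precision summaries plus a `rounded` block at 3
#' significant figures for eyeball comparison with published tables.
#'
#' @param summaries Output of [population_summaries()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
summaries_json <- function(summaries, path = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) == 1L)
  scalars <- as.list(summaries[setdiff(names(summaries), "stratum_rrs")])
  scalars <- lapply(scalars, unname)
  srr <- summaries$stratum_rrs[[1]]
  payload <- c(
    scalars,
    list(
      stratum_rrs = setNames(as.list(srr$rr_c), srr$stratum),
      rounded = lapply(scalars, function(v) if (is.numeric(v)) signif(v, 3) else v)
    )
  )
  out <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          na = "null", pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
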
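#' PAF estimate with provenance
#'
#' Every PAF estimator in the package returns a `paf_result`: the point
#' estimate together with a tag naming the formula that produced it and an
#' echo of the inputs it consumed. The class exists so that results can be
#' printed, compared, serialized and turned into tidy tibbles without losing
#' track of which identification formula was used.
#'
#' @param estimate The attributable fraction (may be negative for a
#'   protective exposure; always < 1).
#' @param formula One of `"levin"`, `"levin_unadjusted"`, `"miettinen_pc"`,
#'   `"miettinen_three"`, `"definition"`, `"eq_binary_em"`,
#'   `"eq_general_em"`, `"levin_general"`, `"miettinen_general"`,
#'   `"miettinen_cases"`.
#' @param inputs Named list echoing the consumed input values.
#' @return An object of class `paf_result`.
#' @name paf_result
NULL

paf_formulas <- c(
  "levin", "levin_unadjusted", "miettinen_pc", "miettinen_three",
  "definition", "eq_binary_em", "eq_general_em",
  "levin_general", "miettinen_general", "miettinen_cases"
)

paf_result <- function(estimate, formula, inputs = list()) {
  formula <- match.arg(formula, paf_formulas)
  structure(
    list(estimate = as.numeric(estimate), formula = formula, inputs = inputs),
    class = "paf_result"
  )
}

#' @export
print.paf_result <- function(x, digits = 3, ...) {
  cat(sprintf("<paf_result> %s\n", x$formula))
  cat(sprintf("  PAF estimate: %s\n", signif(x$estimate, digits)))
  if (length(x$inputs)) {
    scalars <- x$inputs[vapply(x$inputs, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
    if (length(scalars)) {
      cat("  inputs:", paste(sprintf("%s = %s", names(scalars),
                                     signif(unlist(scalars), digits)),
                             collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
as.double.paf_result <- function(x, ...) x$estimate

#' Tidy a PAF result
#'
#' @param x A [paf_result].
#' @param ... Unused.
#' @return `tidy()` gives a one-row tibble with columns `formula` and
#'   `estimate`; `glance()` additionally spreads the scalar inputs into
#'   columns.
#' @exportS3Method generics::tidy
tidy.paf_result <- function(x, ...) {
  tibble(formula = x$formula, estimate = x$estimate)
}

#' @rdname tidy.paf_result
#' @exportS3Method generics::glance
glance.paf_result <- function(x, ...) {
  out <- tibble(formula = x$formula, estimate = x$estimate)
  scalars <- x$inputs[vapply(x$inputs, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
  for (nm in names(scalars)) out[[nm]] <- scalars[[nm]]
  out
}

#' Serialize a PAF result to JSON
#'
#' Full-precision machine output; rounding for human reports happens only in
#' report formatting.
#'
#' @param x A [paf_result].
#' @return A JSON string.
#' @export
paf_result_json <- function(x) {
  stopifnot(inherits(x, "paf_result"))
  jsonlite::toJSON(
    list(formula = x$formula, estimate = x$estimate, inputs = x$inputs),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}
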
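#' Construct a gridded exposure profile
#'
#' An exposure profile carries everything the multi-category / continuous
#' PAF formulas need: the exposure distribution on a grid, the causal
#' relative-risk function \eqn{RR_C(x)} and optionally the unadjusted
#' relative-risk function \eqn{RR_U(x)}, all relative to the minimum-risk
#' exposure value (MREV), the reference level at which both relative risks
#' equal 1.
#'
#' @param data A data frame with columns `x` (exposure values; sorted grid),
#'   `density` (probability masses for `kind = "multicategory"`, density
#'   values for `kind = "continuous"`), `rr_c` (\eqn{RR_C(x) \ge 0}) and
#'   optionally `rr_u`.
#' @param kind `"multicategory"` (masses; exposure codes are non-negative
#'   integers) or `"continuous"` (density on quadrature nodes; integrals are
#'   composite trapezoid on the supplied grid).
#' @param mrev Exposure value treated as the reference; must coincide with a
#'   grid node (interpolation / rescaling of exposure scales is out of
#'   scope). `rr_c` (and `rr_u` if present) must equal 1 there.
#' @param tol Tolerance for the mass sum-to-one check (multicategory).
#'
#' @details Continuous densities are renormalized to integrate to exactly 1
#'   before use, with a warning when the raw trapezoid integral deviates from
#'   1 by more than `1e-3`. A grid-resolution warning fires when the causal
#'   RR jumps by more than a factor 1.5 between adjacent continuous nodes,
#'   since trapezoid quadrature degrades on such grids.
#'
#' @return A tibble of class `exposure_profile` with attributes `kind` and
#'   `mrev`.
#' @examples
#' prof <- exposure_profile(
#'   data.frame(x = 0:2, density = c(0.5, 0.3, 0.2), rr_c = c(1, 2, 4)),
#'   kind = "multicategory"
#' )
#' tidy(paf_levin_general(prof))
#' @export
exposure_profile <- function(data, kind = c("multicategory", "continuous"),
                             mrev = 0, tol = 1e-9) {
  kind <- match.arg(kind)
  if (!is.data.frame(data)) {
    paf_abort("`data` must be a data frame.", "pafbias_error_invalid_profile")
  }
  needed <- c("x", "density", "rr_c")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    paf_abort(sprintf("Profile is missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "pafbias_error_invalid_profile")
  }
  keep <- intersect(c(needed, "rr_u"), names(data))
  x <- arrange(as_tibble(data)[keep], .data$x)
  if (anyDuplicated(x$x)) {
    paf_abort("Exposure grid values must be distinct.", "pafbias_error_invalid_profile")
  }
  if (!is.numeric(x$density) || anyNA(x$density) || any(x$density < 0)) {
    paf_abort("`density` must be non-negative and non-missing.",
              "pafbias_error_invalid_profile")
  }
  if (!is.numeric(x$rr_c) || anyNA(x$rr_c) || any(x$rr_c < 0)) {
    paf_abort("`rr_c` must be non-negative and non-missing.",
              "pafbias_error_invalid_profile")
  }
  if (!any(x$x == mrev)) {
    paf_abort(sprintf("MREV %g must coincide with a grid node.", mrev),
              "pafbias_error_invalid_profile")
  }
  at_ref <- which(x$x == mrev)
  if (abs(x$rr_c[at_ref] - 1) > 1e-8) {
    paf_abort("rr_c must equal 1 at the MREV.", "pafbias_error_invalid_profile")
  }
  if ("rr_u" %in% names(x)) {
    if (!is.numeric(x$rr_u) || anyNA(x$rr_u) || any(x$rr_u < 0)) {
      paf_abort("`rr_u` must be non-negative and non-missing.",
                "pafbias_error_invalid_profile")
    }
    if (abs(x$rr_u[at_ref] - 1) > 1e-8) {
      paf_abort("rr_u must equal 1 at the MREV.", "pafbias_error_invalid_profile")
    }
  }

  if (kind == "multicategory") {
    if (any(x$x < 0) || any(x$x != round(x$x))) {
      paf_abort("Multicategory exposure codes must be non-negative integers.",
                "pafbias_error_invalid_profile")
    }
    x$x <- as.integer(round(x$x))
    total <- sum(x$density)
    if (abs(total - 1) > tol) {
      paf_abort(sprintf("Probability masses sum to %.12g, not 1.", total),
                "pafbias_error_invalid_profile")
    }
  } else {
    if (nrow(x) < 2L) {
      paf_abort("A continuous profile needs at least two grid nodes.",
                "pafbias_error_invalid_profile")
    }
    total <- pracma::trapz(x$x, x$density)
    if (total <= 0) {
      paf_abort("Continuous density integrates to 0.", "pafbias_error_invalid_profile")
    }
    if (abs(total - 1) > 1e-3) {
      warn(sprintf("Density integrates to %.6g; renormalizing to 1.", total),
           class = "pafbias_warning_density_renormalized")
    }
    x$density <- x$density / total
    rr_pos <- x$rr_c[x$rr_c > 0]
    if (length(rr_pos) > 1L) {
      ratio <- exp(abs(diff(log(rr_pos))))
      if (any(ratio > 1.5)) {
        warn("Causal RR changes by more than a factor 1.5 between adjacent grid nodes; the quadrature grid may be too coarse.",
             class = "pafbias_warning_coarse_grid")
      }
    }
  }
  attr(x, "kind") <- kind
  attr(x, "mrev") <- mrev
  class(x) <- c("exposure_profile", class(tibble()))
  x
}

profile_kind <- function(profile) attr(profile, "kind")

assert_profile <- function(profile) {
  if (!inherits(profile, "exposure_profile")) {
    paf_abort("Expected an `exposure_profile` (see `exposure_profile()`).",
              "pafbias_error_invalid_profile")
  }
  invisible(profile)
}

# expectation of per-node values under the profile's exposure distribution
profile_expectation <- function(profile, values) {
  if (profile_kind(profile) == "multicategory") {
    sum(profile$density * values)
  } else {
    pracma::trapz(profile$x, profile$density * values)
  }
}

#' Levin's formula for general exposure distributions
#'
#' \deqn{PAF_L = \frac{E_X[RR_C(X)] - 1}{E_X[RR_C(X)]}}
#' with the expectation a mass-weighted sum (multicategory) or a composite
#' trapezoid integral (continuous). Collapses to [paf_levin()] for a
#' two-point profile. Like its binary parent, it is unbiased only in the
#' absence of confounding.
#'
#' @param profile An [exposure_profile()].
#' @return A [paf_result] with formula tag `"levin_general"`.
#' @export
paf_levin_general <- function(profile) {
  assert_profile(profile)
  e_rr <- profile_expectation(profile, profile$rr_c)
  paf_result((e_rr - 1) / e_rr, "levin_general",
             list(e_rr_c = e_rr, kind = profile_kind(profile)))
}

#' Miettinen's formula for general exposure distributions
#'
#' \deqn{PAF_M = \frac{E_X\left[RR_U(X)\,\frac{RR_C(X)-1}{RR_C(X)}\right]}
#'   {E_X[RR_U(X)]}}
#' For a discrete exposure with levels \eqn{0, \dots, L} this is the
#' summation form whose denominator is
#' \eqn{\pi(0) + \sum_{x \ge 1} \pi(x) RR_U(x)} (the two coincide because
#' \eqn{RR_U} is 1 at the reference); for a continuous exposure both
#' expectations are trapezoid integrals on the supplied grid. Exact under
#' confounding when \eqn{RR_C(x)} is constant within confounder strata.
#'
#' @inheritParams paf_levin_general
#' @return A [paf_result] with formula tag `"miettinen_general"`.
#' @export
paf_miettinen_general <- function(profile) {
  assert_profile(profile)
  if (!"rr_u" %in% names(profile)) {
    paf_abort("Miettinen's general formula needs the unadjusted relative-risk column `rr_u`.",
              "pafbias_error_missing_rr_u")
  }
  bad <- profile$density > 0 & profile$rr_c <= 0
  if (any(bad)) {
    paf_abort(sprintf("rr_c is 0 at exposure value(s) %s carrying probability mass; (RR_C - 1)/RR_C is undefined there.",
                      paste(signif(profile$x[bad], 6), collapse = ", ")),
              "pafbias_error_domain")
  }
  frac <- ifelse(profile$rr_c > 0, (profile$rr_c - 1) / profile$rr_c, 0)
  num <- profile_expectation(profile, profile$rr_u * frac)
  den <- profile_expectation(profile, profile$rr_u)
  paf_result(num / den, "miettinen_general",
             list(e_rr_u = den, kind = profile_kind(profile)))
}

#' Miettinen's formula from the case-conditional exposure distribution
#'
#' \deqn{PAF_M = E_{X \mid Y=1}\left[\frac{RR_C(X) - 1}{RR_C(X)}\right]}
#' Here the profile's `density` column must hold the exposure distribution
#' *among disease cases*, \eqn{\pi_c(x)}. For a binary exposure this reduces
#' to [paf_miettinen_pc()].
#'
#' @param case_profile An [exposure_profile()] whose density slot carries
#'   \eqn{\pi_c(x)}.
#' @return A [paf_result] with formula tag `"miettinen_cases"`.
#' @seealso [case_profile()] to derive \eqn{\pi_c(x)} from a population
#'   profile by Bayes' rule.
#' @export
paf_miettinen_cases <- function(case_profile) {
  assert_profile(case_profile)
  bad <- case_profile$density > 0 & case_profile$rr_c <= 0
  if (any(bad)) {
    paf_abort("rr_c is 0 where the case density is positive.",
              "pafbias_error_domain")
  }
  frac <- ifelse(case_profile$rr_c > 0, (case_profile$rr_c - 1) / case_profile$rr_c, 0)
  paf_result(profile_expectation(case_profile, frac), "miettinen_cases",
             list(kind = profile_kind(case_profile)))
}

#' Case-conditional exposure distribution by Bayes' rule
#'
#' Converts a population exposure profile (with `rr_u`) into the
#' corresponding case-conditional profile:
#' \eqn{\pi_c(x) = RR_U(x)\,\pi(x) / E_X[RR_U(X)]}.
#'
#' @inheritParams paf_levin_general
#' @return An [exposure_profile()] whose density is \eqn{\pi_c(x)}.
#' @export
case_profile <- function(profile) {
  assert_profile(profile)
  if (!"rr_u" %in% names(profile)) {
    paf_abort("Deriving the case density needs the `rr_u` column.",
              "pafbias_error_missing_rr_u")
  }
  e_rr_u <- profile_expectation(profile, profile$rr_u)
  out <- as_tibble(profile)
  out$density <- out$rr_u * out$density / e_rr_u
  suppressWarnings(
    exposure_profile(out, kind = profile_kind(profile), mrev = attr(profile, "mrev"))
  )
}
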
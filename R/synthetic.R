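# run code under a temporary RNG state so generators are reproducible
# without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a synthetic stratified population
#'
#' Describes the generative structure behind a confounder-stratified
#' population with a binary exposure: per-stratum weights, baseline
#' (unexposed) disease risks, causal relative risks and exposure
#' prevalences. Constant `stratum_rrs` means no effect modification on the
#' relative-risk scale; differential `exposure_prevalence_by_stratum` across
#' strata with unequal baseline risks is what creates confounding.
#'
#' @param stratum_weights Probabilities summing to 1 (within `1e-9`), one per
#'   stratum.
#' @param baseline_risks Per-stratum \eqn{P(Y=1 \mid X=0, C=c)} in `(0, 1)`.
#' @param stratum_rrs Per-stratum causal relative risk; a scalar is recycled
#'   (no-effect-modification mode). `baseline * rr` must stay at most 1 in
#'   every stratum.
#' @param exposure_prevalence_by_stratum Per-stratum \eqn{P(X=1 \mid C=c)} in
#'   `[0, 1]`.
#' @param labels Optional stratum labels; defaults to `s1, s2, ...`.
#' @return A list of class `population_spec`.
#' @examples
#' # the generative structure of a classic physical-activity / hypertension
#' # example: 80/20 strata, baselines 0.1/0.2, RR 1.5, exposure 37.5%/75%
#' spec <- population_spec(c(0.8, 0.2), c(0.1, 0.2), 1.5, c(0.375, 0.75))
#' make_population(spec)
#' @export
population_spec <- function(stratum_weights, baseline_risks, stratum_rrs,
                            exposure_prevalence_by_stratum, labels = NULL) {
  n <- length(stratum_weights)
  if (n < 1L) paf_abort("At least one stratum is required.", "pafbias_error_domain")
  if (abs(sum(stratum_weights) - 1) > 1e-9) {
    paf_abort("`stratum_weights` must sum to 1.", "pafbias_error_domain")
  }
  check_prob(stratum_weights, "stratum_weights")
  check_prob(baseline_risks, "baseline_risks", allow_zero = FALSE, allow_one = FALSE)
  if (length(stratum_rrs) == 1L) stratum_rrs <- rep(stratum_rrs, n)
  check_positive(stratum_rrs, "stratum_rrs")
  check_prob(exposure_prevalence_by_stratum, "exposure_prevalence_by_stratum")
  if (length(baseline_risks) != n || length(stratum_rrs) != n ||
      length(exposure_prevalence_by_stratum) != n) {
    paf_abort("All per-stratum vectors must have one entry per stratum.",
              "pafbias_error_domain")
  }
  if (any(baseline_risks * stratum_rrs > 1 + 1e-12)) {
    paf_abort("baseline_risk * stratum_rr exceeds 1 in at least one stratum; exposed risks must stay probabilities.",
              "pafbias_error_invalid_probability")
  }
  if (is.null(labels)) labels <- sprintf("s%d", seq_len(n))
  structure(
    list(
      n_strata = n,
      stratum_weights = as.numeric(stratum_weights),
      baseline_risks = as.numeric(baseline_risks),
      stratum_rrs = as.numeric(stratum_rrs),
      exposure_prevalence_by_stratum = as.numeric(exposure_prevalence_by_stratum),
      labels = as.character(labels)
    ),
    class = "population_spec"
  )
}

#' Realise a stratified population from a spec
#'
#' Cell proportions are `stratum_weight * P(X | stratum)`; exposed-cell risks
#' are `baseline * stratum_rr`. Strata with exposure prevalence 0 or 1
#' contribute a single cell (a stratum fully exposed would lack a reference
#' cell, so exposure prevalence must stay below 1).
#'
#' @param spec A [population_spec()].
#' @return A [stratified_population()].
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (any(spec$exposure_prevalence_by_stratum >= 1)) {
    paf_abort("Exposure prevalence must be < 1 in every stratum (the reference cell would otherwise be empty).",
              "pafbias_error_invalid_probability")
  }
  rows <- purrr::pmap(
    list(spec$labels, spec$stratum_weights, spec$baseline_risks,
         spec$stratum_rrs, spec$exposure_prevalence_by_stratum),
    function(lab, w, b, rr, p) {
      out <- tibble(stratum = lab, exposure = 0L, proportion = w * (1 - p), risk = b)
      if (p > 0) {
        out <- bind_rows(out, tibble(stratum = lab, exposure = 1L,
                                     proportion = w * p, risk = b * rr))
      }
      out
    }
  )
  stratified_population(bind_rows(rows))
}

#' Draw a random population spec
#'
#' Used by the property-test machinery: weights from a flat Dirichlet,
#' baseline risks uniform on `[0.02, 0.4]`, exposure prevalences uniform on
#' `[0.05, 0.95]`, and causal relative risks uniform on
#' `[0.5, min(3, 0.95/baseline)]` so every exposed risk stays below 0.95
#' (headroom keeps all quantities well away from the probability boundary).
#' With `effect_modification = FALSE` a single relative risk is shared by all
#' strata.
#'
#' @param n_strata Number of confounder strata.
#' @param effect_modification Draw stratum-specific relative risks?
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return A [population_spec()].
#' @export
random_population_spec <- function(n_strata = 2L, effect_modification = FALSE,
                                   seed = NULL) {
  with_seed(seed, {
    w <- rgamma(n_strata, shape = 1)
    w <- w / sum(w)
    b <- runif(n_strata, 0.02, 0.4)
    if (effect_modification) {
      rr <- runif(n_strata, 0.5, pmin(3, 0.95 / b))
    } else {
      rr <- runif(1, 0.5, min(3, 0.95 / max(b)))
    }
    p <- runif(n_strata, 0.05, 0.95)
    population_spec(w, b, rr, p)
  })
}

# crude RR of a two-stratum binary population as a function of the
# stratum-2 exposure prevalence, at fixed overall prevalence
.sweep_rr_u <- function(p2, pi, w, b, rr_c) {
  p1 <- (pi - w[2] * p2) / w[1]
  num_mass <- w[1] * p1 * b[1] + w[2] * p2 * b[2]
  den_mass <- w[1] * (1 - p1) * b[1] + w[2] * (1 - p2) * b[2]
  (rr_c * num_mass / pi) / (den_mass / (1 - pi))
}

#' Populations spanning a range of confounding ratios
#'
#' For each requested confounding ratio \eqn{C = RR_C/RR_U}, builds a
#' two-stratum population with a fixed overall exposure prevalence and a
#' fixed (constant-across-strata) causal relative risk whose realized crude
#' relative risk satisfies \eqn{RR_C/RR_U = C}. Confounding is created the
#' way a high-risk stratum attracts exposure: the stratum-wise exposure split
#' is found by bisection on the (monotone) map from split to realized
#' confounding ratio, to `|C - target| < tol`.
#'
#' @param pi Overall exposure prevalence in `(0, 1)`.
#' @param rr_c Constant stratum causal relative risk (> 0);
#'   `rr_c * max(baseline_risks)` must stay at most 0.95.
#' @param c_values Target confounding ratios.
#' @param stratum_weights,baseline_risks Two-stratum geometry; the defaults
#'   (weights 0.8/0.2, baselines 0.1/0.2) mirror the classic
#'   physical-activity example.
#' @param tol Tolerance on the realized confounding ratio.
#' @return A tibble with one row per target: `c_target`, `c_realized`, the
#'   realized `pi`, `rr_u`, `rr_c`, and the population itself in the
#'   `population` list-column.
#' @export
sweep_confounding <- function(pi, rr_c, c_values,
                              stratum_weights = c(0.8, 0.2),
                              baseline_risks = c(0.1, 0.2),
                              tol = 1e-6) {
  check_prob(pi, "pi", allow_zero = FALSE, allow_one = FALSE)
  check_positive(rr_c, "rr_c")
  check_positive(c_values, "c_values")
  if (length(stratum_weights) != 2L || length(baseline_risks) != 2L) {
    paf_abort("The confounding sweep uses exactly two strata.", "pafbias_error_domain")
  }
  if (baseline_risks[1] == baseline_risks[2]) {
    paf_abort("Equal baseline risks make every split unconfounded; choose distinct baseline risks.",
              "pafbias_error_domain")
  }
  if (rr_c * max(baseline_risks) > 0.95) {
    paf_abort("rr_c * max(baseline_risks) exceeds 0.95; no probability headroom.",
              "pafbias_error_invalid_probability")
  }
  w <- stratum_weights / sum(stratum_weights)
  b <- baseline_risks
  eps <- 1e-9
  p2_lo <- max(0, (pi - w[1] * (1 - eps)) / w[2]) + eps
  p2_hi <- min(1 - eps, pi / w[2] - eps)
  if (p2_hi <= p2_lo) {
    paf_abort("No feasible stratum exposure split for this prevalence and weighting.",
              "pafbias_error_infeasible")
  }
  c_at <- function(p2) rr_c / .sweep_rr_u(p2, pi, w, b, rr_c)
  c_ends <- sort(c(c_at(p2_lo), c_at(p2_hi)))

  rows <- lapply(c_values, function(target) {
    if (target < c_ends[1] - tol || target > c_ends[2] + tol) {
      paf_abort(sprintf(
        "Confounding ratio %.6g is infeasible for this geometry; feasible range is [%.6g, %.6g].",
        target, c_ends[1], c_ends[2]),
        "pafbias_error_infeasible")
    }
    f <- function(p2) c_at(p2) - target
    root <- if (abs(f(p2_lo)) < tol) p2_lo
            else if (abs(f(p2_hi)) < tol) p2_hi
            else uniroot(f, c(p2_lo, p2_hi), tol = 1e-14)$root
    p2 <- root
    p1 <- (pi - w[2] * p2) / w[1]
    spec <- population_spec(w, b, rr_c, c(p1, p2))
    pop <- make_population(spec)
    realized_rr_u <- unadjusted_rr(pop)
    tibble(
      c_target = target,
      c_realized = rr_c / realized_rr_u,
      pi = exposure_prevalence(pop),
      rr_u = realized_rr_u,
      rr_c = marginal_causal_rr(pop),
      population = list(pop)
    )
  })
  out <- bind_rows(rows)
  bad <- abs(out$c_realized - out$c_target) >= tol
  if (any(bad)) {
    paf_abort("Bisection failed to reach the target confounding ratio.",
              "pafbias_error_infeasible")
  }
  out
}

#' Synthetic continuous exposure profile
#'
#' Builds a gridded exposure profile with a lognormal-shaped density, a
#' log-linear causal relative-risk function
#' \eqn{RR_C(x) = e^{\beta (x - \mathrm{MREV})}} and, when requested, a
#' log-linear confounding function
#' \eqn{C(x) = RR_C(x)/RR_U(x) = e^{\gamma (x - \mathrm{MREV})}}, so that
#' \eqn{RR_U(x) = e^{(\beta - \gamma)(x - \mathrm{MREV})}}. Both relative
#' risks are exactly 1 at the MREV by construction; `gamma = 0` gives an
#' unconfounded profile. A `confounding` function of `x` (equal to 1 at the
#' MREV) may be supplied instead of the slope.
#'
#' @param n_grid Number of quadrature nodes.
#' @param x_max Upper end of the exposure grid (the grid starts at `mrev`).
#' @param meanlog,sdlog Lognormal density shape parameters.
#' @param log_rr_slope Slope \eqn{\beta} of `log RR_C` per exposure unit.
#' @param log_confounding_slope Slope \eqn{\gamma} of the log confounding
#'   ratio per exposure unit; ignored when `confounding` is given.
#' @param confounding Optional function `C(x)` with `C(mrev) = 1`.
#' @param mrev Minimum-risk exposure value (grid origin).
#' @param with_rr_u Include the unadjusted relative-risk column?
#' @return An [exposure_profile()] of kind `"continuous"`.
#' @export
make_continuous_profile <- function(n_grid = 201, x_max = 5,
                                    meanlog = 0, sdlog = 0.5,
                                    log_rr_slope = 0.3,
                                    log_confounding_slope = 0,
                                    confounding = NULL,
                                    mrev = 0, with_rr_u = TRUE) {
  if (n_grid < 2L) paf_abort("`n_grid` must be at least 2.", "pafbias_error_domain")
  if (x_max <= mrev) paf_abort("`x_max` must exceed `mrev`.", "pafbias_error_domain")
  x <- seq(mrev, x_max, length.out = n_grid)
  dens <- stats::dlnorm(x - mrev, meanlog = meanlog, sdlog = sdlog)
  rr_c <- exp(log_rr_slope * (x - mrev))
  df <- tibble(x = x, density = dens, rr_c = rr_c)
  if (with_rr_u) {
    cfun <- if (!is.null(confounding)) {
      if (!is.function(confounding)) {
        paf_abort("`confounding` must be a function of the exposure value.",
                  "pafbias_error_domain")
      }
      if (abs(confounding(mrev) - 1) > 1e-8) {
        paf_abort("The confounding function must equal 1 at the MREV.",
                  "pafbias_error_domain")
      }
      confounding
    } else {
      function(x) exp(log_confounding_slope * (x - mrev))
    }
    df$rr_u <- df$rr_c / cfun(x)
  }
  suppressWarnings(exposure_profile(df, kind = "continuous", mrev = mrev))
}
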
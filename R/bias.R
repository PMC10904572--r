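#' Relative bias of Levin's formula under confounding
#'
#' With no effect modification on the relative-risk scale, the ratio of
#' Levin's formula (fed the causal relative risk \eqn{RR_C = C \cdot RR_U})
#' to the true PAF has the closed form
#' \deqn{\frac{PAF_L}{PAF} = \frac{1 + \pi(RR_U - 1)}{1 + \pi(C\,RR_U - 1)}
#'   \times C,}
#' where \eqn{C = RR_C / RR_U} is the confounding ratio. The ratio is 1 at
#' \eqn{C = 1}, stays positive for all \eqn{C > 0}, and worsens as the
#' confounding moves away from 1 in either direction.
#'
#' @param pi Exposure prevalence in `(0, 1]` (`pi = 0` is rejected: the PAF
#'   is then 0 and the ratio undefined).
#' @param rr_u Unadjusted relative risk (> 0).
#' @param c Confounding ratio(s) \eqn{RR_C/RR_U} (> 0); vectorised.
#' @return Numeric vector of \eqn{PAF_L / PAF}.
#' @seealso [absolute_bias()], [bias_limits()], [bias_curves()]
#' @export
relative_bias <- function(pi, rr_u, c) {
  check_prob(pi, "pi", allow_zero = FALSE)
  check_positive(rr_u, "rr_u")
  check_positive(c, "c")
  (1 + pi * (rr_u - 1)) / (1 + pi * (c * rr_u - 1)) * c
}

#' Absolute bias of Levin's formula under confounding
#'
#' \eqn{PAF_L - PAF}: Levin's formula at \eqn{RR_C = C\,RR_U} minus the
#' three-variable Miettinen value at the same inputs. It vanishes at
#' \eqn{C = 1} (no confounding) and at \eqn{C = 1/RR_U} (no causal effect,
#' \eqn{RR_C = 1}). The difference is evaluated in factored form,
#' \deqn{\pi(RR_C - 1)\,
#'   \frac{D_U RR_C - RR_U D_C}{D_C\, D_U\, RR_C}, \quad
#'   D_U = 1 + \pi(RR_U - 1),\; D_C = 1 + \pi(RR_C - 1),}
#' so that the cancellation at \eqn{C = 1} is exact in floating point
#' instead of leaving a machine-epsilon residue.
#'
#' @inheritParams relative_bias
#' @return Numeric vector of \eqn{PAF_L - PAF}.
#' @export
absolute_bias <- function(pi, rr_u, c) {
  check_prob(pi, "pi", allow_zero = FALSE)
  check_positive(rr_u, "rr_u")
  check_positive(c, "c")
  rr_c <- c * rr_u
  d_u <- 1 + pi * (rr_u - 1)
  d_c <- 1 + pi * (rr_c - 1)
  pi * (rr_c - 1) * (d_u * rr_c - rr_u * d_c) / (d_c * d_u * rr_c)
}

#' Limiting biases of Levin's formula
#'
#' The analytic limits of the bias functions, never grid extrapolations:
#' * `rel_limit_c_inf` — supremum of the relative bias as \eqn{C \to \infty}:
#'   \eqn{1 + (1-\pi)/(\pi RR_U)}.
#' * `abs_limit_c_inf` — limit of the absolute bias as \eqn{C \to \infty}:
#'   \eqn{1 - \pi RR_U / (1 + \pi(RR_U - 1))}.
#' * `rel_value_at_c_inv_rru` — relative bias as \eqn{C \to 1/RR_U} (where
#'   \eqn{RR_C \to 1} and both PAFs vanish):
#'   \eqn{(1 + \pi(RR_U - 1)) / RR_U}.
#'
#' @inheritParams relative_bias
#' @return A one-row tibble with the three limits.
#' @export
bias_limits <- function(pi, rr_u) {
  check_prob(pi, "pi", allow_zero = FALSE)
  check_positive(rr_u, "rr_u")
  tibble(
    rel_limit_c_inf = 1 + (1 - pi) / (pi * rr_u),
    abs_limit_c_inf = 1 - pi * rr_u / (1 + pi * (rr_u - 1)),
    rel_value_at_c_inv_rru = (1 + pi * (rr_u - 1)) / rr_u
  )
}

#' Bias curves over a grid of confounding ratios
#'
#' Evaluates the relative and absolute bias of Levin's formula — both the
#' "adjusted" version that uses the causal relative risk \eqn{RR_C = C\,RR_U}
#' and the "unadjusted" version that plugs \eqn{RR_U} straight in — over a
#' grid of confounding ratios, against the same true PAF
#' (the three-variable Miettinen value). At \eqn{C = 1/RR_U} the true PAF is
#' 0 and the unadjusted relative bias is returned as `Inf`/`-Inf` as
#' computed.
#'
#' @inheritParams relative_bias
#' @param c_grid Ordered positive confounding ratios. The default is 200
#'   log-spaced points on `[0.2, 5]`; log spacing because the ratio acts
#'   multiplicatively.
#' @return A tibble of class `bias_profile` with columns `c`,
#'   `rel_bias_adj`, `abs_bias_adj`, `rel_bias_unadj`, `abs_bias_unadj`, and
#'   attributes `pi`, `rr_u` and `limits` (see [bias_limits()]). Plot it
#'   with [ggplot2::autoplot()].
#' @examples
#' prof <- bias_curves(0.5, 1.5)
#' head(tidy(prof))
#' @export
bias_curves <- function(pi, rr_u, c_grid = default_c_grid()) {
  check_prob(pi, "pi", allow_zero = FALSE)
  check_positive(rr_u, "rr_u")
  check_positive(c_grid, "c_grid")
  if (is.unsorted(c_grid, strictly = TRUE)) {
    paf_abort("`c_grid` must be strictly increasing.", "pafbias_error_domain")
  }
  paf_true <- vapply(c_grid, function(ci) {
    paf_miettinen_three(pi, rr_u, ci * rr_u)$estimate
  }, numeric(1))
  paf_lu <- paf_levin(pi, rr_u)$estimate
  out <- tibble(
    c = c_grid,
    rel_bias_adj = relative_bias(pi, rr_u, c_grid),
    abs_bias_adj = absolute_bias(pi, rr_u, c_grid),
    rel_bias_unadj = paf_lu / paf_true,
    abs_bias_unadj = paf_lu - paf_true
  )
  attr(out, "pi") <- pi
  attr(out, "rr_u") <- rr_u
  attr(out, "limits") <- bias_limits(pi, rr_u)
  class(out) <- c("bias_profile", class(tibble()))
  out
}

#' @rdname bias_curves
#' @param n Number of grid points.
#' @param c_min,c_max Grid end points.
#' @export
default_c_grid <- function(c_min = 0.2, c_max = 5, n = 200) {
  check_positive(c_min, "c_min")
  check_positive(c_max, "c_max")
  if (c_max <= c_min) {
    paf_abort("`c_max` must exceed `c_min`.", "pafbias_error_domain")
  }
  exp(seq(log(c_min), log(c_max), length.out = n))
}

#' @exportS3Method generics::tidy
tidy.bias_profile <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.bias_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble(pi = attr(x, "pi"), rr_u = attr(x, "rr_u"),
           c_min = min(x$c), c_max = max(x$c), n_grid = nrow(x)),
    attr(x, "limits")
  )
}
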
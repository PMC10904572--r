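---
title: "Attributable fractions under confounding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions under confounding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafbias)
```

## The estimand

The population attributable fraction (PAF) is the fraction of disease risk
that would be removed if the exposure were eliminated:

$$\mathrm{PAF} \;=\; \frac{P(Y = 1) - P(Y_0 = 1)}{P(Y = 1)},$$

where $Y_0$ is the potential outcome under no exposure. `pafbias` represents
a population as a tibble of cells `(stratum, exposure, proportion, risk)` —
joint confounder-by-exposure proportions and conditional risks — built with
`stratified_population()`. Under the identification assumptions below, the
counterfactual risk is obtained by standardisation: within each confounder
stratum, everyone is assigned the stratum's reference-exposure risk, and the
results are averaged over the observed stratum distribution
(`counterfactual_risk()`, `paf_definition()`).

**Assumptions.** (1) Conditional exchangeability: within strata of the
recorded confounder the exposure is as-if randomised. (2) Consistency and
no interference. (3) Positivity: every stratum contains a reference-exposure
cell. These are identification assumptions; the package works at the level
of population quantities and makes no claims about sampling uncertainty.

## The estimators and why they differ

Write $\pi$ for the exposure prevalence, $\pi_c$ for the prevalence among
cases, $RR_U$ for the crude (unadjusted) risk ratio and $RR_C$ for the
causal (confounder-standardised) risk ratio.

* **Levin's formula** $\;\mathrm{PAF}_L = \dfrac{\pi(RR-1)}{1+\pi(RR-1)}$
  (`paf_levin()`). It is exact only when exposure and confounder are
  independent; plugging an adjusted $RR_C$ into it does **not** fix the
  bias, because the formula's denominator implicitly uses the crude risk.
* **Miettinen's case-prevalence formula**
  $\;\mathrm{PAF}_M = \pi_c\,\dfrac{RR-1}{RR}$ (`paf_miettinen_pc()`).
  Exact with the causal RR under a constant stratum RR; under effect
  modification it is exact when the causal RR *among the exposed* is used.
* **The three-variable form**
  $\;\mathrm{PAF} = \dfrac{\pi RR_U}{1+\pi(RR_U-1)}\cdot\dfrac{RR_C-1}{RR_C}$
  (`paf_miettinen_three()`), obtained from the case-prevalence form by the
  Bayes identity $\pi_c = \pi RR_U / (1 + \pi(RR_U - 1))$. It needs only
  summary statistics that published studies usually report.

With $C = RR_C / RR_U$ the confounding ratio, the ratio
$\mathrm{PAF}_L/\mathrm{PAF}$ has the closed form implemented in
`relative_bias()`, with finite limits as $C \to \infty$ and a zero of the
absolute bias at $C = 1$ (`bias_limits()`, `bias_curves()`,
`autoplot()` on the resulting `bias_profile`).

```{r}
s <- population_summaries(read_population_csv(pafbias_example("table1.csv")))
c(true = s$paf,
  levin = paf_levin(s$pi, s$rr_c_marginal)$estimate,
  miettinen = paf_miettinen_three(s$pi, s$rr_u, s$rr_c_marginal)$estimate)
```

## Effect modification

When stratum-specific causal RRs differ, the marginal $RR_C$ is a
case-weighted average and no single-RR formula is exact. The exact
case-weighted decomposition
$\mathrm{PAF} = \sum_{z,x} P(Z{=}z, X{=}x \mid Y{=}1)\,(1 - 1/RR_{zx})$
is implemented in `paf_effect_modification()`; restricting the RR to the
exposed (`causal_rr_exposed()`) restores exactness of the case-prevalence
formula. The shipped fixture `table1_em.csv` demonstrates the residual bias
of the three-variable form (0.346 vs a true 0.385) when the marginal causal
RR is used anyway.

## Multi-category and continuous exposures

`exposure_profile()` holds a grid of exposure values with a mass/density
column and RR functions relative to the minimum-risk exposure value (MREV),
which must be a grid node where both RRs equal 1. Generalisations:

$$\mathrm{PAF}_L = \frac{E[RR_C(X)]-1}{E[RR_C(X)]},\qquad
  \mathrm{PAF}_M = \frac{E[RR_U(X)\,(RR_C(X)-1)/RR_C(X)]}{E[RR_U(X)]},$$

with expectations as sums (multicategory) or trapezoid quadrature
(continuous, via `pracma::trapz`). `case_profile()` converts the population
density to the case density by the Bayes identity
$\pi_c(x) \propto RR_U(x)\,\pi(x)$, and `paf_miettinen_cases()` evaluates
the equivalent case-density form $E_{X\mid Y=1}[(RR_C-1)/RR_C]$.

## Parameter defaults and numerical choices

* **Confounding grid** — `default_c_grid()` spans $C \in [0.2, 5]$ with 200
  log-spaced points: symmetric on the log scale around $C = 1$, wide enough
  that both asymptotic regimes are visible, fine enough that the curves are
  smooth at plotting resolution.
* **Exact zero at C = 1** — `absolute_bias()` is evaluated in a factored
  form whose numerator cancels bitwise at $C = 1$, so the unconfounded point
  on a bias curve is exactly $(1, 0)$ rather than within rounding of it.
* **Trapezoid quadrature** — chosen over higher-order rules because profiles
  arrive as tabulated grids (no analytic integrand), it is exact for the
  piecewise-linear densities used as internal oracles, and its error is
  transparent. A warning (`pafbias_warning_*`) fires when adjacent $RR_C$
  values differ by more than a factor of 1.5, signalling a grid too coarse
  for the curvature; densities off unit mass by more than $10^{-3}$ are
  renormalised with a warning.
* **Root finding** — `sweep_confounding()` holds $RR_C$ fixed and varies one
  stratum's exposure prevalence, a map that is monotone in the realized
  crude RR whenever the baseline risks differ; `stats::uniroot` at tolerance
  $10^{-14}$ achieves $|C - \text{target}| < 10^{-6}$. Infeasible targets
  abort with the feasible range in the message.
* **Synthetic generator defaults** — `random_population_spec()` draws
  stratum weights from Dirichlet(1), baseline risks from $U(0.02, 0.4)$,
  stratum RRs from $U(0.5, \min(3, 0.95/\text{baseline}))$ and exposure
  prevalences from $U(0.05, 0.95)$. The 0.95 cap keeps every cell risk a
  valid probability with headroom; the ranges cover protective through
  strong harmful effects without degenerate near-0/1 probabilities.
  Degenerate inputs (zero-mass strata, risks at the cap) are rejected at
  construction rather than silently repaired.
* **Test sizes** — the package's own randomized identity suites run 50
  replicates per property in the unit tests and 200 in the end-to-end
  suites; these sizes were chosen to finish in seconds while exercising 1–5
  strata and both effect-modification regimes.

## What the synthetic data does and does not emulate

The generators produce exact population tables — joint proportions and
conditional risks — not samples. They emulate confounded exposure–outcome
structure, effect modification, and controlled confounding ratios; they do
not emulate sampling noise, measurement error, model misspecification, or
time-varying exposure.

## Limitations

All results are identification-level: given a correct stratified population,
the formulas are exact identities, but no standard errors or confidence
intervals are produced, and no adjustment for unmeasured confounding or
transportability to other populations is attempted. The MREV for general
exposures is taken as known and on the grid; estimating it is out of scope.
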
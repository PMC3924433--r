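---
title: "Age-period-cohort models for former-smoker prevalence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-period-cohort models for former-smoker prevalence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcprev)
```

## The data and the model

The unit of analysis is a *Lexis table*: former-smoker counts $y_{ap}$
among $n_{ap}$ respondents for 5-year age bands $a$ (25–29 … 80–84, so
$A \le 12$) crossed with 5-year calendar periods $p$ (e.g. 1980–1984 …
2005–2009). The diagonals of this grid are birth cohorts,
$c = p - a$ applied to band midpoints, so an $A \times P$ grid induces
$A + P - 1$ overlapping 5-year cohorts labelled by central birth year
(the 12 × 6 grid gives 17 cohorts, 1900 … 1980). Corner cohorts are seen
in a single cell, central ones in up to $\min(A, P)$ cells, so their
effects are estimated with very different precision.

Former smoking is not a rare event (prevalences of 10–40%), so the usual
Poisson approximation for APC rate models is inappropriate; the model is
grouped-binomial with logit link:

$$y_{ap} \sim \mathrm{Bin}(n_{ap},\, p_{ap}), \qquad
\mathrm{logit}(p_{ap}) = \mu + \alpha_a + \beta_p + \gamma_{c(a,p)}.$$

**Assumptions.** Cells are independent given the effects (no survey
design effects — the generator and the fitters both work at the
binomial-cell level); effects are additive on the logit scale (no
age-by-period interaction); each 5-year cohort is treated as a point
labelled by its central birth year, ignoring the 10-year birth span a
diagonal actually covers.

## Identifiability

Since $c = p - a$, adding a slope $s$ per band step to the age curve,
$-s$ to the period curve and $s$ to the cohort curve (plus any constants)
leaves every $p_{ap}$ unchanged: only the *non-linear* shapes of the
three curves and one overall trend are identified. The package fixes the
gauge with the convention that **the secular trend belongs to the cohort
scale**: all three curves are stored sum-to-zero and the period curve is
detrended (zero least-squares slope), the removed drift being reassigned
along the cohort (and, necessarily, age) indices. This is implemented
once (`normalize_scenario`, `normalize_effects`) and used by the
generator, by comparisons of classical estimates, and inside the MCMC
recentring, so recovered curves are comparable across routes. The
epidemiological rationale: quitting is primarily a generational
phenomenon (awareness of harm accumulates over cohorts), while period
shocks — advertising bans, tax rises, smoke-free laws — are transient
deviations around that trend.

## Classical fitting

`fit_binomial_glm` fits the AC and AP submodels by maximum likelihood
(binomial GLM, corner constraints: first age band, first period, and a
configurable reference cohort at zero — 1930 for men, 1950 for women,
the generations most exposed to smoking). The engine is `stats::glm`,
i.e. IRLS with step-halving; an independent `optim` oracle in the test
suite confirms the optimum to $10^{-6}$ in log-likelihood on small grids.

The full APC model is fitted by the **two-step procedure**
(`fit_apc_two_step`): step 1 fits AC; step 2 fits the period factor in a
second binomial GLM with the step-1 fit held as a fixed offset. The
offset enters by default as the step-1 *linear predictor* (logit of the
AC fitted probabilities): this is the coherent binomial analogue of the
log-fitted-value offset of Poisson practice, since adding the period
contrast on the link scale preserves the binomial likelihood structure.
The literal log-fitted-*count* offset is available
(`offset_type = "log_fitted"`) for comparison; the two conventions give
genuinely different period contrasts, which is why the choice is
explicit. Degrees of freedom are counted as parameters actually
estimated across both steps ($A + C - 1$ in step 1, $P$ in step 2), and
$\mathrm{AIC} = -2\ell + 2\,\mathrm{df}$ with $\ell$ the final (step-2)
log-likelihood. Deviance nesting
$0 \le \mathrm{dev(APC)} \le \mathrm{dev(AP)}, \mathrm{dev(AC)}$ is
guaranteed against AC by construction; against AP it is not a theorem
for the two-step fit (step 1 is frozen), but it held on every randomized
table in the property suite and is asserted there with a $10^{-6}$
tolerance.

Cells with an entire factor level at $y = 0$ or $y = n$ (separation
risk) are flagged, the fit proceeds with a warning, and standard
deviations for the affected levels are reported as unavailable.

## The Bayesian model

Each effect curve gets a first-order random-walk (RW1) prior: adjacent
differences iid $N(0, \tau^{-1})$, one innovation precision per time
scale, with $\tau \sim \mathrm{Gamma}(\text{shape}, \text{rate})$
hyperpriors and a diffuse $N(0, 100)$ prior on $\mu$. Defaults are shape
1, rate 0.01 on all three scales — weakly informative (prior mean
precision 100, i.e. innovation SD $\approx$ 0.1 on the logit scale, with
large spread). These defaults are a declared design decision, not a
reconstruction of any published appendix; `sensitivity_scan` quantifies
how little they matter (rates spanning 0.001–0.1 moved desk-scale
projections by well under the credible-interval width in our tests, with
the largest differences in the last projection year).

**Sampler** (`src/apc_gibbs.cpp`): Metropolis-within-Gibbs.
Single-site Gaussian random-walk proposals for $\mu$ and every effect
entry, with per-parameter step sizes adapted toward 44% acceptance
during burn-in only (adaptation stops at the burn-in boundary, so the
retained chain is a valid fixed-kernel MCMC); conjugate
$\mathrm{Gamma}(\text{shape} + m/2,\ \text{rate} + \mathrm{SS}/2)$
updates for each precision, verified distributionally against the closed
form by a KS test in the suite. After each sweep the effects are
recentred by the likelihood-invariant gauge transformation described
above. The RW1 priors are invariant to the level shifts; the slope
reassignment changes the RW1 densities in mutually compensating
directions and the diffuse intercept prior is flat at the scale of these
shifts, so identified quantities are unaffected — the suite checks that
cell probabilities and second differences agree between recentred and
unconstrained runs, and that the sampler's marginal matches a dense
1-D integration of the posterior on a single-cell table.

Defaults are desk-scale: 4 chains × 25,000 iterations, 10,000 burn-in,
thinning 5 (a production-scale 10^6/5×10^5 single-chain run is
`mcmc_config(1e6, 5e5)`). With the compiled sampler a default fit of a
12 × 6 table takes a few seconds.

**Projection.** With horizon $H$, each retained draw is extended by $H$
future period effects and $H$ new cohort effects from the RW1
predictive at that draw's precision: future effects random-walk from the
last observed values, so projected intervals widen with the horizon
(asserted as a property). Cohorts already observed keep their posterior
draws as they age into future cells — this is what transports the
estimated cohort trend into the projection. Age-cumulated prevalence is
computed per draw via `cumulate_prevalence`; future periods have no
respondent counts, so the age weights of the last observed period are
carried forward (age-structure-held-constant convention).

**Cumulation weights.** Whether published cumulated curves weight age
groups by respondents, by population or equally is generally unstated;
the package defaults to respondent weights per period (the
survey-consistent crude prevalence) and exposes `"equal"` and numeric
weights as alternatives.

## Geweke diagnostic

`geweke` compares the first 10% of a chain with the last 50%,
standardised by spectral-density-at-zero estimates of each window. The
spectral density is estimated by an AIC-selected AR($p$) fit (the
convention of the classical implementations) rather than a short
lag-window periodogram: a Bartlett window of length $n/10$ leaves only
$\sim 20$ effective degrees of freedom, which inflates the nominal 5%
exceedance of $|z| > 1.96$ to $\sim 8\%$ on iid chains, while the AR
estimator keeps nearly full degrees of freedom for well-mixed chains
(measured 5.9% over 1,000 iid chains of length 2,000 in the acceptance
suite). Zero-variance chains are reported as undefined and excluded
from exceedance counts.

## The synthetic world

`scenario_preset` fixes the stated world the tests exercise:
12 × 6 grid, ~3,000 respondents per cell (two genders × 12 bands from
surveys of ~54,000 persons, averaged over a 5-year period window), and
logit-scale curves with the qualitative structure reported for Italian
former smokers: an age effect growing with age (strong in men, nearly
flat in women), a small period effect peaking in the 1992–2002 window
and declining near-linearly afterwards, and a monotone increasing cohort
effect. Magnitudes are not published anywhere, so they are package
choices, made once: the period peak is ±0.2 on the logit scale and the
cohort curve is a scaled `tanh` over the 17 cohorts. Two features of the
choice matter:

* The cohort curve is *curved*, not a straight line. An exactly linear
  cohort effect is pure drift — the gauge transformation can absorb it
  entirely into age and period, the full APC model can then never
  outperform AP, and the documented deviance ordering
  ($\Delta\text{-Dev(AC)} > \Delta\text{-Dev(AP)}$, APC lowest AIC,
  AC comparable to APC on the 1995–2009 window) becomes unattainable.
  Curvature is also the realistic case: generational change accelerates
  and saturates.
* The period curve's decline after the peak is near-linear, so the
  1995–2009 sub-window contains almost no *non-linear* period signal —
  reproducing the finding that the cohort effect suffices there.

What a green test does **not** establish: anything about real survey
estimates. The generator emulates binomial cell counts only — no
two-stage cluster sampling, no survey weights, no non-response, no
measurement error in self-reported smoking status — and published
headline numbers (prevalence projections for 2030, printed deviance
tables) depend on microdata that is not deposited; the packaged
end-of-smoking computation uses the published projected smoker series as
*input*, not as something the model re-derives.

## Numerical choices and degenerate inputs

* Band midpoints use the arithmetic mean of inclusive integer years
  (1980–1984 → 1982), which makes the 1900/1980 cohort endpoints exact.
* `end_of_smoking` extrapolates the line through the last two strictly
  positive tabulated values and rounds the crossing to the nearest
  multiple of 5 years (the tabulation step) — the operationalisation of
  an "around year X" statement; with only one positive value before a
  tabulated zero, the segment to that zero is used. Rounding is pushed
  *up* in the (rare) case the rounded year would precede the last
  positive year. Increasing tails have no finite crossing and error.
* Negative smoker complements are clamped at zero at presentation;
  pre-clamp values are retained (and sum to exactly 100 with the other
  two series) for the crossing computation and the property tests.
* Fully degenerate tables (all cells 0 or all $n$) are rejected by the
  sampler; the shrinkage limit $\tau \to \infty$ needs precisions around
  $10^{10}$ before the prior truly dominates a 3,000-per-cell
  likelihood — at $10^6$ the data still win, which the test suite
  documents explicitly.
* All stochastic entry points take explicit seeds; chain $k$ of an MCMC
  run uses `seed + k - 1`, and `sensitivity_scan` reuses the same seed
  across prior settings so that reported differences are prior-driven.

## Known limitations

* The two-step APC fit is not a joint maximum-likelihood fit; its
  step-1 estimates ignore the period effect, which is the price of the
  identified standard deviations.
* Single-site Metropolis updates mix slowly for strongly correlated
  effect curves; desk-scale defaults leave a few percent of monitored
  parameters above the Geweke threshold on hard tables. Longer runs (the
  production preset) or blocked updates would improve this.
* RW1 projections are driftless by construction: the projected *period*
  effect stays at its last level, and all projected growth comes from
  cohort succession. A model with drift or RW2 smoothing would
  extrapolate differently; RW2 priors are out of scope.
* The recentring step is exact for the likelihood and level-invariant
  priors but interacts with the diffuse intercept prior; with
  `mu_var` well above the effect scale (default 100) the effect is
  negligible, and the suite's integration check bounds it empirically.
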
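# ---------------------------------------------------------------------------
# Synthetic-data scenarios: ground-truth APC effect curves on the logit scale
# plus a binomial sampling layer, used for parameter-recovery and projection
# tests. Stored curves are identifiability-normalised (see normalize_scenario)
# so that they are the recoverable contrasts.
# ---------------------------------------------------------------------------

#' Define a ground-truth APC scenario
#'
#' A scenario fixes the true cell probabilities of a Lexis grid through the
#' logit-additive model `p_ap = plogis(mu + alpha_a + beta_p + gamma_c(a,p))`
#' plus a per-cell respondent count. On construction the curves are put into
#' the package's identifiability normalisation (see
#' [normalize_scenario()]), so the stored curves are exactly the contrasts a
#' fitter can recover.
#'
#' @param intercept grand intercept `mu` on the logit scale.
#' @param age_curve numeric length A: age effects (logit scale).
#' @param period_curve numeric length P: period effects.
#' @param cohort_curve numeric length A + P - 1: cohort effects, ordered
#'   from the oldest cohort.
#' @param n_per_cell respondents per cell: a positive integer scalar or an
#'   A x P matrix.
#' @param age_lower,period_start band definitions as in [lexis_table()].
#' @param gender stratum label attached to simulated tables.
#' @param seed default RNG seed used by [simulate_table()].
#' @return object of class `apc_scenario`.
#' @export
scenario <- function(intercept, age_curve, period_curve, cohort_curve,
                     n_per_cell = 3000,
                     age_lower = seq(25, by = 5, length.out = length(age_curve)),
                     period_start = seq(1980, by = 5, length.out = length(period_curve)),
                     gender = "unspecified", seed = 1L) {
  A <- length(age_curve); P <- length(period_curve)
  if (length(cohort_curve) != A + P - 1)
    stop(sprintf("cohort_curve must have length A + P - 1 = %d, got %d",
                 A + P - 1, length(cohort_curve)))
  if (is.matrix(n_per_cell)) {
    if (!all(dim(n_per_cell) == c(A, P))) stop("n_per_cell matrix must be A x P")
  } else if (length(n_per_cell) != 1 || n_per_cell < 1) {
    stop("n_per_cell must be a positive scalar or an A x P matrix")
  }
  obj <- structure(list(intercept = intercept, age_curve = as.numeric(age_curve),
                        period_curve = as.numeric(period_curve),
                        cohort_curve = as.numeric(cohort_curve),
                        n_per_cell = n_per_cell, age_lower = age_lower,
                        period_start = period_start, gender = gender,
                        seed = as.integer(seed)),
                   class = "apc_scenario")
  normalize_scenario(obj)
}

#' Identifiability normalisation of scenario curves
#'
#' The logit-additive APC predictor is unchanged by (i) moving constants
#' between the intercept and each curve and (ii) adding a slope `s` per band
#' step to the age curve, `-s` to the period curve and `s` to the cohort
#' curve (since cohort index = period index - age index + A). The package
#' fixes this by storing all three curves sum-to-zero with the period curve
#' additionally detrended (zero least-squares slope), the removed drift being
#' reassigned to the cohort (and age) indices -- the convention that the
#' secular trend belongs to the cohort effect. The map is idempotent and
#' leaves every cell probability unchanged.
#'
#' @param sc an `apc_scenario`.
#' @return the scenario with normalised curves and adjusted intercept.
#' @export
normalize_scenario <- function(sc) {
  stopifnot(inherits(sc, "apc_scenario"))
  nz <- .apc_normalize(sc$intercept, sc$age_curve, sc$period_curve, sc$cohort_curve)
  sc$intercept <- nz$mu
  sc$age_curve <- nz$age
  sc$period_curve <- nz$period
  sc$cohort_curve <- nz$cohort
  sc
}

#' @export
print.apc_scenario <- function(x, ...) {
  cat(sprintf("APC scenario (%s): %d ages x %d periods, mu = %.3f, n/cell ~ %s\n",
              x$gender, length(x$age_curve), length(x$period_curve),
              x$intercept, format(mean(x$n_per_cell))))
  invisible(x)
}

#' True cell probabilities of a scenario
#'
#' @param sc an `apc_scenario`.
#' @return A x P matrix of probabilities
#'   `plogis(mu + alpha_a + beta_p + gamma_c)`, all in (0, 1).
#' @examples
#' sc <- scenario(-2, rep(0, 3), rep(0, 2), rep(0, 4))
#' true_prevalence(sc)[1, 1]  # plogis(-2) ~ 0.1192
#' @export
true_prevalence <- function(sc) {
  stopifnot(inherits(sc, "apc_scenario"))
  A <- length(sc$age_curve); P <- length(sc$period_curve)
  eta <- outer(sc$age_curve, sc$period_curve, "+") + sc$intercept
  cpos <- outer(seq_len(A), seq_len(P), function(a, p) p - a + A)
  eta <- eta + matrix(sc$cohort_curve[cpos], A, P)
  plogis(eta)
}

#' Simulate a Lexis table from a scenario
#'
#' Draws `y_ap ~ Binomial(n_ap, p_ap)` independently per cell from the
#' scenario's true probabilities; reproducible under a fixed seed.
#'
#' @param sc an `apc_scenario`.
#' @param seed RNG seed; defaults to the scenario's own seed.
#' @return a [lexis_table()].
#' @export
simulate_table <- function(sc, seed = sc$seed) {
  p <- true_prevalence(sc)
  A <- nrow(p); P <- ncol(p)
  n <- if (is.matrix(sc$n_per_cell)) sc$n_per_cell else matrix(sc$n_per_cell, A, P)
  set.seed(seed)
  y <- matrix(rbinom(A * P, size = as.vector(n), prob = as.vector(p)), A, P)
  lexis_table(y, n, age_lower = sc$age_lower, period_start = sc$period_start,
              gender = sc$gender)
}

#' Extend a scenario with future periods
#'
#' Appends `extra_periods` future periods, continuing the period curve by
#' holding its last value constant (the detrended period effect carries no
#' secular trend to continue) and the cohort curve by its fitted linear
#' trend, which is where the normalisation assigns the drift. The result is
#' ground truth for projection-recovery tests; the already-normalised
#' observed-window curves are left untouched (no re-normalisation).
#'
#' @param sc an `apc_scenario`.
#' @param extra_periods number of future 5-year periods (>= 0).
#' @return an `apc_scenario` covering P + extra_periods periods.
#' @export
extend_scenario <- function(sc, extra_periods) {
  stopifnot(inherits(sc, "apc_scenario"), extra_periods >= 0)
  if (extra_periods == 0) return(sc)
  P <- length(sc$period_curve); C <- length(sc$cohort_curve)
  sc$period_curve <- c(sc$period_curve, rep(sc$period_curve[P], extra_periods))
  cidx <- seq_len(C)
  slope <- if (C > 1) coef(lm(sc$cohort_curve ~ cidx))[2] else 0
  sc$cohort_curve <- c(sc$cohort_curve,
                       sc$cohort_curve[C] + slope * seq_len(extra_periods))
  sc$period_start <- c(sc$period_start,
                       max(sc$period_start) + BAND_WIDTH * seq_len(extra_periods))
  class(sc) <- "apc_scenario"
  sc
}

#' Built-in scenario presets
#'
#' `italy_male` and `italy_female` emulate the qualitative structure of
#' former-smoker prevalence from repeated Italian health surveys on the
#' 12 age-band (25-29 ... 80-84) by 6 period (1980-1984 ... 2005-2009) grid:
#' an age effect growing with age (strongly in men, weakly in women), a
#' small period effect peaking around 1992-2002, a monotonically increasing
#' cohort effect, and roughly 3,000 respondents per cell. `null` has all
#' curves at zero (every cell probability 0.5).
#'
#' @param name one of `"italy_male"`, `"italy_female"`, `"null"`.
#' @param n_per_cell,seed overrides passed to [scenario()].
#' @return an `apc_scenario`.
#' @examples
#' sc <- scenario_preset("italy_male")
#' range(true_prevalence(sc))
#' @export
scenario_preset <- function(name = c("italy_male", "italy_female", "null"),
                            n_per_cell = 3000, seed = 1L) {
  name <- match.arg(name)
  A <- 12; P <- 6
  switch(name,
    italy_male = scenario(
      intercept = -1.4,
      age_curve = seq(-0.9, 0.9, length.out = A),
      period_curve = c(-0.22, -0.02, 0.18, 0.24, 0.20, 0.16),
      cohort_curve = 1.1 * tanh(seq(-1.5, 1.5, length.out = A + P - 1)) / tanh(1.5),
      n_per_cell = n_per_cell, gender = "male", seed = seed),
    italy_female = scenario(
      intercept = -2.2,
      age_curve = seq(-0.15, 0.15, length.out = A),
      period_curve = c(-0.22, -0.02, 0.18, 0.24, 0.20, 0.16),
      cohort_curve = 1.4 * tanh(seq(-1.5, 1.5, length.out = A + P - 1)) / tanh(1.5),
      n_per_cell = n_per_cell, gender = "female", seed = seed),
    null = scenario(
      intercept = 0,
      age_curve = rep(0, A), period_curve = rep(0, P),
      cohort_curve = rep(0, A + P - 1),
      n_per_cell = n_per_cell, gender = "null", seed = seed))
}
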
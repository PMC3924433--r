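# ---------------------------------------------------------------------------
# APC effect vectors on the logit scale and the identifiability
# normalisation shared by the scenario generator, the classical fitter and
# the MCMC sampler.
# ---------------------------------------------------------------------------

#' Bundle APC effect estimates
#'
#' @param mu intercept (logit scale).
#' @param age,period,cohort effect vectors of lengths A, P, A + P - 1.
#' @param cohort_labels central birth years for the cohort entries.
#' @param reference_cohort birth year whose effect is pinned at zero under
#'   the corner-constraint parameterisation (`NA` if none).
#' @return object of class `apc_effects`.
#' @export
apc_effects <- function(mu, age, period, cohort, cohort_labels = NULL,
                        reference_cohort = NA) {
  if (length(cohort) != length(age) + length(period) - 1)
    stop("cohort must have length A + P - 1")
  structure(list(mu = unname(mu), age = unname(age), period = unname(period),
                 cohort = unname(cohort), cohort_labels = cohort_labels,
                 reference_cohort = reference_cohort),
            class = "apc_effects")
}

#' @export
print.apc_effects <- function(x, ...) {
  cat(sprintf("APC effects: mu = %.4f, A = %d, P = %d, C = %d (reference cohort %s)\n",
              x$mu, length(x$age), length(x$period), length(x$cohort),
              as.character(x$reference_cohort)))
  invisible(x)
}

# Core normalisation: curves sum-to-zero, period curve detrended via the
# likelihood-invariant slope transfer to age/cohort indices. Returns a list
# with elements mu, age, period, cohort. Idempotent.
.apc_normalize <- function(mu, age, period, cohort) {
  A <- length(age); P <- length(period)
  pidx <- seq_len(P)
  s <- if (P > 1) coef(lm(period ~ pidx))[[2]] else 0
  period <- period - s * pidx
  age <- age + s * seq_len(A)
  cohort <- cohort + s * seq_len(A + P - 1)
  mu <- mu - s * A
  for (v in c("age", "period", "cohort")) {
    x <- get(v)
    mu <- mu + mean(x)
    assign(v, x - mean(x))
  }
  list(mu = mu, age = age, period = period, cohort = cohort)
}

#' Put APC effects into the package's identified parameterisation
#'
#' Applies the same transformation as [normalize_scenario()]: all three
#' curves sum to zero and the period curve has zero least-squares slope, the
#' drift being reassigned along the cohort (and age) indices. Cell
#' probabilities are unchanged, so estimates from any constraint convention
#' (corner constraints, sum-to-zero) become directly comparable.
#'
#' @param x an `apc_effects`.
#' @return an `apc_effects` in the normalised parameterisation
#'   (`reference_cohort` is dropped, as no corner remains pinned).
#' @export
normalize_effects <- function(x) {
  stopifnot(inherits(x, "apc_effects"))
  nz <- .apc_normalize(x$mu, x$age, x$period, x$cohort)
  apc_effects(nz$mu, nz$age, nz$period, nz$cohort,
              cohort_labels = x$cohort_labels, reference_cohort = NA)
}

#' Linear predictor and cell probabilities implied by APC effects
#' @param x an `apc_effects`.
#' @return A x P matrix of probabilities on the Lexis grid.
#' @export
effects_prevalence <- function(x) {
  A <- length(x$age); P <- length(x$period)
  cpos <- outer(seq_len(A), seq_len(P), function(a, p) p - a + A)
  plogis(x$mu + outer(x$age, x$period, "+") + matrix(x$cohort[cpos], A, P))
}
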
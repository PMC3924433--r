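# ---------------------------------------------------------------------------
# Bayesian APC model: binomial likelihood, RW1 smoothing priors on the age,
# period and cohort effects with Gamma hyperpriors on the innovation
# precisions, fitted by Metropolis-within-Gibbs (compiled sampler in
# src/apc_gibbs.cpp) and projected through the RW1 predictive.
# ---------------------------------------------------------------------------

#' Prior settings for the Bayesian APC model
#'
#' Each effect curve (age, period, cohort) gets a first-order random-walk
#' (RW1) prior: adjacent differences are iid `N(0, 1/tau)` with a
#' `Gamma(shape, rate)` hyperprior on the innovation precision `tau`. The
#' intercept gets a diffuse normal prior. Defaults are weakly informative
#' (shape 1, rate 0.01, i.e. prior mean precision 100 with large spread);
#' robustness to this choice is what [sensitivity_scan()] quantifies.
#'
#' @param shape,rate Gamma hyperparameters; scalars are recycled to the
#'   three scales (order: age, period, cohort). Must be strictly positive.
#' @param mu_mean,mu_var mean and variance of the normal prior on the
#'   intercept.
#' @return object of class `bayes_priors`.
#' @export
bayes_priors <- function(shape = 1, rate = 0.01, mu_mean = 0, mu_var = 100) {
  shape <- rep_len(as.numeric(shape), 3)
  rate <- rep_len(as.numeric(rate), 3)
  if (any(shape <= 0) || any(rate <= 0) || mu_var <= 0)
    stop("Gamma shapes/rates and mu_var must be strictly positive")
  structure(list(shape = setNames(shape, c("age", "period", "cohort")),
                 rate = setNames(rate, c("age", "period", "cohort")),
                 mu_mean = mu_mean, mu_var = mu_var),
            class = "bayes_priors")
}

#' MCMC run settings
#'
#' Defaults are desk-scale: 4 chains of 25,000 iterations with a 10,000
#' burn-in, thinned by 5 (12,000 retained draws). `mcmc_config(1e6, 5e5)`
#' reproduces a production-scale single-chain run.
#'
#' @param iterations sweeps per chain (must exceed `burn_in`).
#' @param burn_in discarded initial sweeps (>= 0).
#' @param thin keep every `thin`-th post-burn-in sweep (>= 1).
#' @param chains number of independent chains (>= 1).
#' @param seed base RNG seed; chain `k` uses `seed + k - 1`.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 25000, burn_in = 10000, thin = 5,
                        chains = 4, seed = 1L) {
  if (iterations <= burn_in || burn_in < 0 || thin < 1 || chains < 1)
    stop("need iterations > burn_in >= 0, thin >= 1, chains >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log unnormalised posterior density of the Bayesian APC model
#'
#' Binomial log-likelihood (including the binomial coefficients) at
#' `p = plogis(mu + alpha + beta + gamma)` plus the RW1 log-densities of the
#' first differences of each curve, the Gamma log-hyperpriors on the three
#' precisions, and the normal log-prior on the intercept.
#'
#' @param effects an [apc_effects()] with dimensions matching `x`.
#' @param precisions numeric length 3 (age, period, cohort), all positive.
#' @param x a `lexis_table`.
#' @param priors a [bayes_priors()].
#' @return scalar log density (finite for interior values).
#' @export
log_unnormalized_posterior <- function(effects, precisions, x,
                                       priors = bayes_priors()) {
  stopifnot(inherits(effects, "apc_effects"), inherits(x, "lexis_table"))
  precisions <- rep_len(as.numeric(precisions), 3)
  vals <- c(effects$mu, effects$age, effects$period, effects$cohort, precisions)
  if (any(!is.finite(vals)) || any(precisions <= 0))
    stop("effects must be finite and precisions strictly positive")
  A <- nrow(x$y); P <- ncol(x$y)
  if (length(effects$age) != A || length(effects$period) != P)
    stop("effect dimensions do not match the table")
  p <- effects_prevalence(effects)
  ll <- sum(dbinom(x$y, x$n, p, log = TRUE))
  rw1 <- function(v, tau) sum(dnorm(diff(v), 0, 1 / sqrt(tau), log = TRUE))
  lp <- rw1(effects$age, precisions[1]) + rw1(effects$period, precisions[2]) +
    rw1(effects$cohort, precisions[3]) +
    sum(dgamma(precisions, shape = priors$shape, rate = priors$rate, log = TRUE)) +
    dnorm(effects$mu, priors$mu_mean, sqrt(priors$mu_var), log = TRUE)
  ll + lp
}

# row-wise cumulative sum via multiplication with an upper-triangular matrix
row_cumsum <- function(m) {
  H <- ncol(m)
  m %*% upper.tri(diag(H), diag = TRUE)
}

#' Draw from the posterior of the Bayesian APC model
#'
#' Runs the compiled Metropolis-within-Gibbs sampler: single-site
#' random-walk Metropolis updates for the intercept and effect curves
#' (step sizes adapted to ~44% acceptance during burn-in), conjugate Gamma
#' updates for the three RW1 innovation precisions, and after every sweep a
#' recentring by the likelihood-invariant identifiability transformation
#' (all curves sum-to-zero, period curve detrended with the drift assigned
#' to the cohort scale -- the same parameterisation as
#' [normalize_scenario()]). With `horizon > 0`, each retained draw is
#' extended by `horizon` future period effects and `horizon` new cohort
#' effects drawn from the RW1 predictive at that draw's precision.
#'
#' @param x a `lexis_table`.
#' @param priors a [bayes_priors()].
#' @param config an [mcmc_config()].
#' @param horizon number of future 5-year periods to project (>= 0).
#' @param update_effects if `FALSE`, the effects are held at their initial
#'   values and only the precisions are sampled (their full conditional is
#'   then the closed-form Gamma posterior) -- used for conjugacy checking.
#' @param init optional named list overriding initial values (`mu`,
#'   `alpha`, `beta`, `gamma`).
#' @param recentre if `FALSE`, skip the per-sweep identifiability
#'   recentring and sample the unconstrained parameterisation (identified
#'   quantities such as cell probabilities are unaffected; mainly for
#'   checking that invariance).
#' @return object of class `apc_posterior`: draw matrices `mu` (S), `alpha`
#'   (S x A), `beta` (S x (P + horizon)), `gamma` (S x (A+P-1+horizon)),
#'   `tau` (S x 3), `chain` ids, per-chain Metropolis `acceptance` rates,
#'   and the table, priors, config and horizon used.
#' @export
sample_posterior <- function(x, priors = bayes_priors(), config = mcmc_config(),
                             horizon = 0, update_effects = TRUE, init = NULL,
                             recentre = TRUE) {
  validate_lexis(x)
  stopifnot(inherits(priors, "bayes_priors"), inherits(config, "mcmc_config"),
            horizon >= 0)
  if (all(x$y == 0) || all(x$y == x$n))
    stop("table is fully degenerate (all cells 0 or all cells n)")
  A <- nrow(x$y); P <- ncol(x$y); C <- A + P - 1
  H <- as.integer(horizon)
  mu0 <- qlogis(sum(x$y) / sum(x$n))
  draws <- list(); accept <- list()
  for (k in seq_len(config$chains)) {
    set.seed(config$seed + k - 1L)
    ini <- list(mu = mu0, alpha = rnorm(A, 0, 0.05), beta = rnorm(P, 0, 0.05),
                gamma = rnorm(C, 0, 0.05))
    if (!is.null(init)) ini[names(init)] <- init
    res <- apc_gibbs_cpp(x$y, x$n, ini$mu, ini$alpha, ini$beta, ini$gamma,
                         tau_init = rep(10, 3),
                         prior_shape = priors$shape, prior_rate = priors$rate,
                         mu_mean = priors$mu_mean, mu_var = priors$mu_var,
                         iterations = config$iterations,
                         burn_in = config$burn_in, thin = config$thin,
                         update_effects = update_effects,
                         recentre = update_effects && recentre)
    S <- length(res$mu)
    if (H > 0) {
      # RW1 predictive extensions, one path per retained draw
      sd_b <- 1 / sqrt(res$tau[, 2]); sd_c <- 1 / sqrt(res$tau[, 3])
      inc_b <- matrix(rnorm(S * H, 0, rep(sd_b, H)), S, H)
      inc_c <- matrix(rnorm(S * H, 0, rep(sd_c, H)), S, H)
      res$beta <- cbind(res$beta, res$beta[, P] + row_cumsum(inc_b))
      res$gamma <- cbind(res$gamma, res$gamma[, C] + row_cumsum(inc_c))
    }
    res$chain <- rep(k, S)
    draws[[k]] <- res
    accept[[k]] <- res$accept
  }
  out <- list(
    mu = unlist(lapply(draws, `[[`, "mu")),
    alpha = do.call(rbind, lapply(draws, `[[`, "alpha")),
    beta = do.call(rbind, lapply(draws, `[[`, "beta")),
    gamma = do.call(rbind, lapply(draws, `[[`, "gamma")),
    tau = do.call(rbind, lapply(draws, `[[`, "tau")),
    chain = unlist(lapply(draws, `[[`, "chain")),
    acceptance = accept, table = x, priors = priors, config = config,
    horizon = H)
  colnames(out$tau) <- c("age", "period", "cohort")
  class(out) <- "apc_posterior"
  out
}

#' @export
print.apc_posterior <- function(x, ...) {
  cat(sprintf(
    "APC posterior (%s): %d draws (%d chain(s)), grid %d x %d, horizon %d\n",
    x$table$gender, length(x$mu), max(x$chain), nrow(x$table$y),
    ncol(x$table$y), x$horizon))
  invisible(x)
}

# S x (A * (P+H)) matrix of per-cell prevalence draws, cells column-major
# over the (possibly extended) grid
posterior_prevalence_draws <- function(samples) {
  A <- nrow(samples$table$y)
  PH <- ncol(samples$beta)
  S <- length(samples$mu)
  out <- matrix(NA_real_, S, A * PH)
  for (p in seq_len(PH)) {
    for (a in seq_len(A)) {
      cpos <- p - a + A
      out[, (p - 1) * A + a] <-
        plogis(samples$mu + samples$alpha[, a] + samples$beta[, p] +
               samples$gamma[, cpos])
    }
  }
  out
}

#' Fitted and projected prevalence with credible intervals
#'
#' Summarises the posterior prevalence draws cell by cell (posterior mean
#' and central credible interval) over the observed periods ("fitted") and
#' the projection horizon, and cumulates each draw over age via
#' [cumulate_prevalence()] to give the age-cumulated series. Future periods
#' have no respondent counts, so the age weights of the last observed
#' period are carried forward.
#'
#' @param samples an `apc_posterior` from [sample_posterior()].
#' @param level credible level (default 0.95).
#' @param weights passed to [cumulate_prevalence()].
#' @return object of class `apc_projection`: `period_central` (observed +
#'   future), `observed` (logical mask), matrices `mean`, `lower`, `upper`
#'   (A x (P + horizon)), vectors `cum_mean`, `cum_lower`, `cum_upper`, the
#'   observed age-cumulated prevalence `cum_observed` (NA for future
#'   periods), and `cum_draws` (draws of the cumulated series).
#' @export
project_prevalence <- function(samples, level = 0.95,
                               weights = "respondents") {
  stopifnot(inherits(samples, "apc_posterior"))
  x <- samples$table
  A <- nrow(x$y); P <- ncol(x$y); H <- samples$horizon
  PH <- P + H
  pr <- posterior_prevalence_draws(samples)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  cell_mean <- matrix(colMeans(pr), A, PH)
  cell_q <- apply(pr, 2, quantile, probs = qs)
  lower <- matrix(cell_q[1, ], A, PH)
  upper <- matrix(cell_q[2, ], A, PH)
  # age weights per period; carry the last observed period forward
  w <- if (is.character(weights) && weights[1] == "respondents")
    cbind(x$n, matrix(rep(x$n[, P], H), A, H))
  else if (is.character(weights)) matrix(1, A, PH)
  else matrix(rep_len(weights, A), A, PH)
  if (any(colSums(w) == 0)) stop("weights must not be all zero")
  S <- nrow(pr)
  cum_draws <- matrix(NA_real_, S, PH)
  for (p in seq_len(PH))
    cum_draws[, p] <- pr[, (p - 1) * A + seq_len(A)] %*% w[, p] / sum(w[, p])
  cum_q <- apply(cum_draws, 2, quantile, probs = qs)
  period_central <- c(x$periods$central,
                      if (H > 0) max(x$periods$central) + BAND_WIDTH * seq_len(H))
  structure(list(
    gender = x$gender, ages = x$ages, period_central = period_central,
    observed = c(rep(TRUE, P), rep(FALSE, H)),
    mean = cell_mean, lower = lower, upper = upper,
    cum_mean = colMeans(cum_draws), cum_lower = cum_q[1, ],
    cum_upper = cum_q[2, ],
    cum_observed = c(cumulate_prevalence(x), rep(NA_real_, H)),
    cum_draws = cum_draws, level = level, horizon = H),
    class = "apc_projection")
}

#' @export
print.apc_projection <- function(x, ...) {
  cat(sprintf("APC prevalence projection (%s): %d fitted + %d projected periods\n",
              x$gender, sum(x$observed), sum(!x$observed)))
  df <- data.frame(period = x$period_central,
                   cumulated = round(100 * x$cum_mean, 2),
                   lower = round(100 * x$cum_lower, 2),
                   upper = round(100 * x$cum_upper, 2),
                   observed = ifelse(x$observed, round(100 * x$cum_observed, 2), NA))
  print(df, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Geweke convergence diagnostic
# ---------------------------------------------------------------------------

# spectral density at frequency zero via an AIC-selected autoregressive
# fit (the convention of the classical Geweke implementations): for a
# well-mixed chain the selected order is ~0 and the estimate keeps nearly
# the full degrees of freedom, so the z-scores stay close to N(0,1);
# variance of the window mean is spectrum0(x)/N
spectrum0 <- function(x) {
  fit <- try(ar(x, aic = TRUE, order.max = min(length(x) - 1, 10 * log10(length(x)))),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(var(x))
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  if (!is.finite(s0) || s0 <= 0) s0 <- var(x)
  s0
}

#' Geweke convergence z-score for one chain
#'
#' Compares the mean of the first `first_fraction` of the chain with the
#' mean of the last `last_fraction`, standardised by spectral-density-at-zero
#' estimates of each window's variance of the mean. Values of `|z|` above
#' ~1.96 indicate the chain had not reached its stationary distribution.
#'
#' @param chain numeric vector, length >= 100.
#' @param first_fraction,last_fraction window fractions in (0, 1) with
#'   `first_fraction + last_fraction <= 1`.
#' @return scalar z; `NA` (undefined) for zero-variance windows.
#' @export
geweke <- function(chain, first_fraction = 0.1, last_fraction = 0.5) {
  chain <- as.numeric(chain)
  N <- length(chain)
  if (N < 100) stop("chain must have length >= 100")
  if (first_fraction <= 0 || last_fraction <= 0 ||
      first_fraction + last_fraction > 1)
    stop("window fractions must lie in (0,1) and not overlap")
  n1 <- floor(first_fraction * N)
  n2 <- floor(last_fraction * N)
  x1 <- chain[seq_len(n1)]
  x2 <- chain[seq.int(N - n2 + 1, N)]
  if (var(x1) == 0 || var(x2) == 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sqrt(spectrum0(x1) / n1 + spectrum0(x2) / n2)
}

#' Geweke report over all monitored parameters of a posterior
#'
#' Applies [geweke()] per chain to every monitored scalar: the intercept,
#' each age/period/cohort effect (including projected extensions) and the
#' three precisions.
#'
#' @param samples an `apc_posterior`.
#' @param threshold flag level for `|z|` (default 1.96).
#' @return data frame with `parameter`, `chain`, `z`, `flagged`; attributes
#'   `threshold`, `n_monitored`, `n_flagged`, `n_undefined` and
#'   `frac_flagged` (undefined chains are excluded from the counts).
#' @export
geweke_report <- function(samples, threshold = 1.96) {
  stopifnot(inherits(samples, "apc_posterior"))
  mats <- cbind(mu = samples$mu,
                `colnames<-`(samples$alpha, paste0("age", seq_len(ncol(samples$alpha)))),
                `colnames<-`(samples$beta, paste0("period", seq_len(ncol(samples$beta)))),
                `colnames<-`(samples$gamma, paste0("cohort", seq_len(ncol(samples$gamma)))),
                `colnames<-`(samples$tau, paste0("tau_", colnames(samples$tau))))
  chains <- sort(unique(samples$chain))
  rows <- do.call(rbind, lapply(chains, function(k) {
    sel <- samples$chain == k
    z <- apply(mats[sel, , drop = FALSE], 2, geweke)
    data.frame(parameter = colnames(mats), chain = k, z = unname(z))
  }))
  rows$flagged <- !is.na(rows$z) & abs(rows$z) > threshold
  attr(rows, "threshold") <- threshold
  attr(rows, "n_monitored") <- sum(!is.na(rows$z))
  attr(rows, "n_flagged") <- sum(rows$flagged)
  attr(rows, "n_undefined") <- sum(is.na(rows$z))
  attr(rows, "frac_flagged") <- sum(rows$flagged) / max(1, sum(!is.na(rows$z)))
  rows
}

# ---------------------------------------------------------------------------
# Prior sensitivity
# ---------------------------------------------------------------------------

#' Scan robustness of projections to the Gamma hyperpriors
#'
#' Re-runs [sample_posterior()] + [project_prevalence()] for each prior
#' setting in `prior_grid` with a common seed (so differences are
#' prior-driven, not Monte-Carlo noise), and reports, per projection year,
#' the maximum pairwise absolute difference of the posterior mean
#' age-cumulated prevalence in percentage points, plus whether each
#' alternate's mean falls inside the first (baseline) setting's credible
#' interval.
#'
#' @param x a `lexis_table`.
#' @param prior_grid list of [bayes_priors()] (length >= 2); the first is
#'   the baseline.
#' @param config an [mcmc_config()]; the same seed is used for every
#'   setting.
#' @param horizon future periods (>= 1 for a meaningful scan).
#' @return list with `years` (projection years), `max_diff_pp` (per-year
#'   max pairwise difference, percentage points), `means_pct` (settings x
#'   years), `inside_baseline_ci` (logical, settings x years) and
#'   `baseline_ci` (2 x years, percent).
#' @export
sensitivity_scan <- function(x, prior_grid, config = mcmc_config(),
                             horizon = 4) {
  if (length(prior_grid) < 2) stop("prior_grid must contain >= 2 settings")
  projs <- lapply(prior_grid, function(pr)
    project_prevalence(sample_posterior(x, pr, config, horizon = horizon)))
  fut <- !projs[[1]]$observed
  years <- projs[[1]]$period_central[fut]
  means <- 100 * do.call(rbind, lapply(projs, function(p) p$cum_mean[fut]))
  colnames(means) <- years
  base_lo <- 100 * projs[[1]]$cum_lower[fut]
  base_hi <- 100 * projs[[1]]$cum_upper[fut]
  inside <- t(apply(means, 1, function(m) m >= base_lo & m <= base_hi))
  colnames(inside) <- years
  list(years = years,
       max_diff_pp = apply(means, 2, max) - apply(means, 2, min),
       means_pct = means,
       inside_baseline_ci = inside,
       baseline_ci = rbind(lower = base_lo, upper = base_hi))
}
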
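quick_config <- function(seed = 1, chains = 2, iterations = 6000,
                         burn_in = 2000, thin = 4) {
  mcmc_config(iterations, burn_in, thin, chains, seed)
}

test_that("log posterior matches a term-by-term oracle to 1e-10", {
  priors <- bayes_priors(shape = c(1, 2, 0.5), rate = c(0.01, 0.1, 1))
  for (seed in 1:5) {
    tab <- random_lexis(400 + seed, A = 4, P = 3)
    set.seed(seed)
    eff <- apc_effects(rnorm(1), rnorm(4), rnorm(3), rnorm(6))
    tau <- rgamma(3, 2, 1)
    expect_equal(log_unnormalized_posterior(eff, tau, tab, priors),
                 oracle_log_posterior(eff, tau, tab, priors),
                 tolerance = 1e-10)
  }
})

test_that("symmetric half-count table gives the closed-form likelihood", {
  tab <- lexis_table(matrix(10, 3, 2), matrix(20, 3, 2))
  priors <- bayes_priors()
  eff <- apc_effects(0, rep(0, 3), rep(0, 2), rep(0, 4))
  lp <- log_unnormalized_posterior(eff, c(1, 1, 1), tab, priors)
  lik_expected <- 6 * (lchoose(20, 10) + 20 * log(0.5))
  # at all-zero effects the RW1 terms are 6 standard-normal densities at 0
  prior_expected <- 6 * dnorm(0, log = TRUE) +
    sum(dgamma(c(1, 1, 1), shape = priors$shape, rate = priors$rate, log = TRUE)) +
    dnorm(0, 0, 10, log = TRUE)
  expect_equal(lp, lik_expected + prior_expected, tolerance = 1e-10)
  # doubling one precision moves only that scale's RW1 + Gamma terms
  lp2 <- log_unnormalized_posterior(eff, c(2, 1, 1), tab, priors)
  m <- 2  # age has A - 1 = 2 first differences (all zero here)
  delta_expected <- m * 0.5 * log(2) +
    dgamma(2, priors$shape[1], rate = priors$rate[1], log = TRUE) -
    dgamma(1, priors$shape[1], rate = priors$rate[1], log = TRUE)
  expect_equal(lp2 - lp, unname(delta_expected), tolerance = 1e-10)
  expect_error(log_unnormalized_posterior(eff, c(-1, 1, 1), tab, priors),
               "positive")
  eff$mu <- Inf
  expect_error(log_unnormalized_posterior(eff, c(1, 1, 1), tab, priors),
               "finite")
})

test_that("precision updates agree with the conjugate Gamma posterior", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 3))
  A <- 12; P <- 6; C <- 17
  set.seed(99)
  init <- list(mu = -1, alpha = rnorm(A, 0, 0.3), beta = rnorm(P, 0, 0.3),
               gamma = rnorm(C, 0, 0.3))
  priors <- bayes_priors(shape = 1, rate = 0.01)
  cfg <- mcmc_config(iterations = 4100, burn_in = 100, thin = 1, chains = 1,
                     seed = 4)
  smp <- sample_posterior(tab, priors, cfg, update_effects = FALSE,
                          init = init)
  for (k in 1:3) {
    v <- list(init$alpha, init$beta, init$gamma)[[k]]
    shape_post <- priors$shape[k] + 0.5 * (length(v) - 1)
    rate_post <- priors$rate[k] + 0.5 * sum(diff(v)^2)
    ks <- suppressWarnings(
      ks.test(smp$tau[, k], pgamma, shape = shape_post, rate = rate_post))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("shrinkage limit reduces to the intercept-only GLM", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 21))
  # precision ~ 1e10: prior penalty dwarfs the likelihood's pull on any
  # effect structure; start at the degenerate point since steps are ~1e-5
  tight <- bayes_priors(shape = 1e12, rate = 1e2)
  smp <- sample_posterior(tab, tight, quick_config(seed = 8),
                          init = list(alpha = rep(0, 12), beta = rep(0, 6),
                                      gamma = rep(0, 17)))
  pm <- matrix(colMeans(posterior_prevalence_draws(smp)), 12, 6)
  p0 <- plogis(qlogis(sum(tab$y) / sum(tab$n)))
  expect_true(all(abs(pm - p0) < 0.003))
})

test_that("sampler marginal matches dense integration on a single cell", {
  # 1x1 grid: after recentring all effects sit in mu, whose posterior is a
  # one-dimensional integral we can evaluate on a grid
  tab <- lexis_table(matrix(30, 1, 1), matrix(100, 1, 1))
  cfg <- mcmc_config(iterations = 30000, burn_in = 5000, thin = 2,
                     chains = 1, seed = 12)
  smp <- sample_posterior(tab, bayes_priors(), cfg)
  expect_true(all(smp$alpha == 0) && all(smp$beta == 0) && all(smp$gamma == 0))
  eta <- seq(-3, 1, length.out = 8001)
  lp <- dbinom(30, 100, plogis(eta), log = TRUE) +
    dnorm(eta, 0, 10, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  m_true <- sum(w * eta)
  sd_true <- sqrt(sum(w * (eta - m_true)^2))
  expect_equal(mean(smp$mu), m_true, tolerance = 0.02)
  expect_equal(sd(smp$mu), sd_true, tolerance = 0.1)
})

test_that("identified quantities are invariant to the recentring convention", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 14))
  cfg <- quick_config(seed = 5, iterations = 12000, burn_in = 4000)
  s1 <- sample_posterior(tab, config = cfg, recentre = TRUE)
  s2 <- sample_posterior(tab, config = cfg, recentre = FALSE)
  p1 <- colMeans(posterior_prevalence_draws(s1))
  p2 <- colMeans(posterior_prevalence_draws(s2))
  expect_lt(max(abs(p1 - p2)), 0.01)
  # second differences of the age curve are identified too
  D2 <- t(diff(diag(12), differences = 2))
  d1 <- colMeans(s1$alpha %*% D2)
  d2 <- colMeans(s2$alpha %*% D2)
  expect_lt(max(abs(d1 - d2)), 0.05)
})

test_that("runs are reproducible under the config seed", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 1))
  cfg <- quick_config(seed = 3, chains = 1, iterations = 1500, burn_in = 500)
  s1 <- sample_posterior(tab, config = cfg, horizon = 2)
  s2 <- sample_posterior(tab, config = cfg, horizon = 2)
  expect_identical(s1$mu, s2$mu)
  expect_identical(s1$beta, s2$beta)  # includes the RW1 predictive draws
  expect_true(all(unlist(s1$acceptance[[1]][c("alpha", "beta", "gamma", "mu")]) > 0))
})

test_that("credible intervals widen with the projection horizon", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 6))
  smp <- sample_posterior(tab, config = quick_config(seed = 6), horizon = 4)
  proj <- project_prevalence(smp)
  fut <- which(!proj$observed)
  width <- proj$upper[, fut] - proj$lower[, fut]
  # per age, on average over draws: each extra horizon step adds variance
  mean_width <- colMeans(width)
  expect_true(all(diff(mean_width) > -1e-3))
  expect_gt(mean_width[4], mean_width[1])
  cum_width <- (proj$cum_upper - proj$cum_lower)[fut]
  expect_true(all(diff(cum_width) > -1e-3))
})

test_that("zero-innovation limit freezes projections at the last fit", {
  # pure age effect: no secular trend, so nothing for the drift convention
  # to reassign, and degenerate period/cohort RWs pin the future to the fit
  sc <- scenario(-1.4, seq(-0.9, 0.9, length.out = 12), rep(0, 6),
                 rep(0, 17), n_per_cell = 3000, gender = "male", seed = 4)
  tab <- simulate_table(sc)
  frozen <- bayes_priors(shape = c(1, 1e8, 1e8), rate = c(0.01, 100, 100))
  smp <- sample_posterior(tab, frozen, quick_config(seed = 9), horizon = 3)
  proj <- project_prevalence(smp)
  last_fit <- proj$mean[, max(which(proj$observed))]
  for (h in which(!proj$observed))
    expect_lt(max(abs(proj$mean[, h] - last_fit)), 0.005)
})

test_that("horizon 0 yields a fitted-only projection", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 2))
  proj <- project_prevalence(sample_posterior(tab, config = quick_config()))
  expect_true(all(proj$observed))
  expect_equal(dim(proj$mean), c(12L, 6L))
  # good fit: posterior mean tracks the observed cumulated prevalence
  expect_lt(max(abs(proj$cum_mean - proj$cum_observed)), 0.01)
})

test_that("geweke flags what it should and rejects what it cannot", {
  expect_true(is.na(geweke(rep(1, 500))))
  expect_error(geweke(rnorm(50)), "length")
  expect_error(geweke(rnorm(500), 0.6, 0.5), "overlap")
  set.seed(15)
  drift <- c(rnorm(400, 0, 1), rnorm(600, 5, 1))  # 5-sigma mean step
  expect_gt(abs(geweke(drift)), 10)
  expect_lt(abs(geweke(rnorm(1000, 0, 1))), 5)
})

test_that("geweke_report monitors every stored parameter", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 5))
  smp <- sample_posterior(tab, config = quick_config(chains = 2), horizon = 1)
  rep_ <- geweke_report(smp)
  # mu + 12 ages + 7 periods + 18 cohorts + 3 precisions, per chain
  expect_equal(nrow(rep_), 2 * (1 + 12 + 7 + 18 + 3))
  expect_true(all(c("parameter", "chain", "z", "flagged") %in% names(rep_)))
  expect_equal(attr(rep_, "threshold"), 1.96)
  expect_lte(attr(rep_, "n_flagged"), attr(rep_, "n_monitored"))
  expect_lt(attr(rep_, "frac_flagged"), 0.25)
})

test_that("sensitivity scan is null for identical settings, ordered otherwise", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 10))
  cfg <- quick_config(seed = 2, chains = 1, iterations = 3000, burn_in = 1000)
  p <- bayes_priors()
  same <- sensitivity_scan(tab, list(p, p), cfg, horizon = 3)
  expect_true(all(same$max_diff_pp == 0))
  expect_error(sensitivity_scan(tab, list(p), cfg), ">= 2")
  grid <- list(bayes_priors(rate = 0.001), bayes_priors(rate = 0.01),
               bayes_priors(rate = 0.1))
  scan <- sensitivity_scan(tab, grid, quick_config(seed = 2), horizon = 4)
  expect_length(scan$max_diff_pp, 4)
  # prior influence grows toward the last projection year
  expect_gt(unname(scan$max_diff_pp[4]), unname(scan$max_diff_pp[1]))
  expect_true(all(scan$inside_baseline_ci))
})
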
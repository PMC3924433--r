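test_that("a saturated grid has deviance exactly zero", {
  tab <- toy_table(3, 2)
  sat <- fit_binomial_glm(tab, "saturated")
  expect_equal(sat$deviance, 0, tolerance = 1e-8)
  # 2x2 grid: age + cohort already has one parameter per cell
  small <- toy_table(2, 2)
  expect_equal(fit_binomial_glm(small, "AC")$deviance, 0, tolerance = 1e-8)
  expect_equal(fit_apc_two_step(small)$deviance, 0, tolerance = 1e-8)
})

test_that("AC/AP estimates attain the likelihood of a brute-force optimizer", {
  # oracle: derivative-free/generic optimisation of the same constrained
  # binomial log-likelihood (helper-tables.R), grids up to 4x3
  for (dims in list(c(3, 2), c(2, 3), c(4, 3))) {
    tab <- random_lexis(100 + dims[1] * 10 + dims[2], A = dims[1], P = dims[2])
    for (model in c("AC", "AP")) {
      fit <- fit_binomial_glm(tab, model)
      expect_equal(fit$loglik, oracle_loglik(tab, model), tolerance = 1e-6)
      expect_true(fit$converged)
    }
  }
})

test_that("corner constraints pin the stated entries at zero", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 5))
  fit <- fit_apc_two_step(tab)
  e <- fit$effects
  expect_equal(e$age[1], 0)
  expect_equal(e$period[1], 0)
  expect_equal(e$reference_cohort, 1930)
  expect_equal(e$cohort[match(1930, e$cohort_labels)], 0)
  expect_equal(fit$df_model, 12 + 17 + 6 - 1)
  # female default reference
  tabf <- simulate_table(scenario_preset("italy_female", seed = 5))
  expect_equal(fit_apc_two_step(tabf)$effects$reference_cohort, 1950)
  expect_error(fit_binomial_glm(tab, "AC", reference_cohort = 1830),
               "not present")
})

test_that("fitted probabilities are invariant to relabelling the cohorts", {
  tab <- random_lexis(21, A = 4, P = 3)
  shifted <- lexis_table(tab$y, tab$n, age_lower = tab$ages$lower,
                         period_start = tab$periods$start + 15,
                         gender = tab$gender)
  coh <- enumerate_cohorts(tab)$cohort
  ref <- coh[3]
  f1 <- fit_apc_two_step(tab, reference_cohort = ref)
  f2 <- fit_apc_two_step(shifted, reference_cohort = ref + 15)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-9)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-9)
})

test_that("step 2 finds no period effect when none was simulated", {
  A <- 12; P <- 6
  sc <- scenario(-1.2, seq(-0.8, 0.8, length.out = A), rep(0, P),
                 1.0 * tanh(seq(-1.5, 1.5, length.out = A + P - 1)),
                 n_per_cell = 20000, gender = "male", seed = 31)
  tab <- simulate_table(sc)
  fit <- fit_apc_two_step(tab)
  free <- 2:P  # first period is the corner
  expect_true(all(abs(fit$effects$period[free]) <
                    3 * fit$effect_sd$period[free]))
  # with nothing left for step 2 to explain, its deviance stays at the AC one
  ac <- fit_binomial_glm(tab, "AC")
  expect_lt(ac$deviance - fit$deviance, qchisq(0.999, df = P - 1) + 1)
})

test_that("the fitted period curve peaks where the scenario's does", {
  sc <- scenario_preset("italy_male", n_per_cell = 20000, seed = 17)
  tab <- simulate_table(sc)
  fit <- normalize_effects(fit_apc_two_step(tab)$effects)
  expect_equal(which.max(fit$period), which.max(sc$period_curve))
  expect_gt(cor(fit$period, sc$period_curve), 0.95)
  expect_gt(cor(fit$age, sc$age_curve), 0.99)
  expect_gt(cor(fit$cohort, sc$cohort_curve), 0.99)
})

test_that("model comparison recovers the generating structure", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 2))
  cmp <- compare_models(tab)
  expect_equal(cmp$model, c("APC", "AP", "AC"))
  expect_equal(cmp$model[which.min(cmp$aic)], "APC")
  expect_true(is.na(cmp$delta_dev[1]))
  expect_true(all(cmp$delta_dev[-1] > 0))
  # AC-generated data: nested-model AIC arithmetic keeps AC within 2(P-1)
  sc_ac <- scenario(-1.2, seq(-0.8, 0.8, length.out = 12), rep(0, 6),
                    tanh(seq(-1.5, 1.5, length.out = 17)),
                    n_per_cell = 3000, seed = 13)
  cmp_ac <- compare_models(simulate_table(sc_ac))
  expect_lt(abs(cmp_ac$aic[cmp_ac$model == "AC"] -
                cmp_ac$aic[cmp_ac$model == "APC"]), 2 * (6 - 1))
})

test_that("period dominates over cohort curvature on the full window only", {
  # qualitative structure of the preset world: dropping the period effect
  # costs more deviance than dropping the cohort effect on 1980-2009, while
  # on the 1995-2009 window AC is comparable to the full APC
  tab <- simulate_table(scenario_preset("italy_male", seed = 2))
  cmp <- compare_models(tab)
  d <- setNames(cmp$delta_dev, cmp$model)
  expect_gt(d["AC"], d["AP"])
  late <- compare_models(lexis_subset(tab, c(1995, 2000, 2005)))
  dl <- setNames(late$delta_dev, late$model)
  expect_lt(dl["AC"], 0.1 * d["AC"])
  expect_lt(abs(late$aic[late$model == "AC"] - late$aic[late$model == "APC"]),
            0.1 * abs(cmp$aic[cmp$model == "AC"] - cmp$aic[cmp$model == "APC"]))
})

test_that("deviance nesting holds on randomized inputs", {
  for (seed in 1:10) {
    tab <- random_lexis(300 + seed, A = sample(3:8, 1), P = sample(3:6, 1))
    cmp <- compare_models(tab)
    dev <- setNames(cmp$deviance, cmp$model)
    expect_gte(dev["AC"] - dev["APC"], -1e-6)
    expect_gte(dev["AP"] - dev["APC"], -1e-6)
    expect_gte(dev["APC"], -1e-8)
  }
})

test_that("degenerate all-zero levels are flagged with unavailable SDs", {
  tab <- random_lexis(55, A = 4, P = 3)
  tab$y[2, ] <- 0  # an entire age band with no former smokers
  expect_warning(fit <- fit_binomial_glm(tab, "AP"), "separation")
  expect_match(fit$flags, "age")
  expect_true(is.na(fit$effect_sd$age[2]))
})

test_that("the literal log-fitted-count offset variant stays available", {
  tab <- simulate_table(scenario_preset("italy_male", seed = 9))
  f1 <- fit_apc_two_step(tab, offset_type = "logit")
  f2 <- fit_apc_two_step(tab, offset_type = "log_fitted")
  expect_s3_class(f2, "apc_fit")
  expect_true(all(is.finite(f2$effects$period)))
  expect_gte(f2$deviance, 0)
  # the two offset conventions are genuinely different models
  expect_false(isTRUE(all.equal(f1$effects$period, f2$effects$period)))
})
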
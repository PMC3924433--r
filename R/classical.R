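# ---------------------------------------------------------------------------
# Classical maximum-likelihood APC fitting for grouped binomial prevalence:
# AC and AP models directly, the full APC through the two-step procedure
# that fits AC first and then a period effect on top of the AC fit held as
# an offset -- resolving the identifiability problem by attributing the
# secular trend to the cohort effect.
# ---------------------------------------------------------------------------

# long format with age/period/cohort factors, column-major over the grid
lexis_long <- function(x) {
  A <- nrow(x$y); P <- ncol(x$y)
  coh <- cohort_grid(x)
  data.frame(
    y = as.vector(x$y), n = as.vector(x$n),
    age = factor(rep(x$ages$central, P), levels = x$ages$central),
    period = factor(rep(x$periods$central, each = A), levels = x$periods$central),
    cohort = factor(as.vector(coh), levels = sort(unique(as.vector(coh)))))
}

#' Default reference cohort for a table
#'
#' The cohort corner constraint is placed at the generation most exposed to
#' cigarette smoking: the 1930 birth cohort for men and 1950 for women. If
#' the exact year is absent from the table's cohort set the nearest
#' available cohort is used.
#'
#' @param x a `lexis_table`.
#' @return a central birth year present in the table.
#' @export
default_reference_cohort <- function(x) {
  target <- if (grepl("^f", tolower(x$gender))) 1950 else 1930
  coh <- sort(unique(as.vector(cohort_grid(x))))
  coh[which.min(abs(coh - target))]
}

# levels whose cells are all y==0 or all y==n (complete separation risk)
degenerate_levels <- function(df, fac) {
  lv <- levels(df[[fac]])
  bad <- vapply(lv, function(l) {
    s <- df[[fac]] == l
    all(df$y[s] == 0) || all(df$y[s] == df$n[s])
  }, logical(1))
  lv[bad]
}

# pull a factor's coefficients (and SEs) back into a full per-level vector,
# with the constrained baseline level exactly zero
extract_factor <- function(fit, fac, lev) {
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  est <- setNames(numeric(length(lev)), lev)
  sdv <- setNames(numeric(length(lev)), lev)
  nm <- paste0(fac, lev)
  hit <- nm %in% names(cf)
  est[hit] <- cf[nm[hit]]
  sdv[hit] <- se[nm[hit]]
  list(est = est, sd = sdv)
}

new_apc_fit <- function(model_tag, table, effects, effect_sd, deviance, aic,
                        df_model, converged, loglik, fitted, flags) {
  structure(list(model_tag = model_tag, gender = table$gender,
                 ages = table$ages, periods = table$periods,
                 effects = effects, effect_sd = effect_sd,
                 deviance = deviance, aic = aic, df_model = df_model,
                 converged = converged, loglik = loglik, fitted = fitted,
                 flags = flags),
            class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf("Binomial %s fit (%s): deviance %.2f on %d parameters, AIC %.2f%s\n",
              x$model_tag, x$gender, x$deviance, x$df_model, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit a binomial age-cohort or age-period model
#'
#' Maximum-likelihood fit of a grouped-binomial GLM with logit link on the
#' Lexis grid: `AC` uses age + cohort factors, `AP` age + period. Corner
#' constraints fix the first age band and first period at zero and the
#' cohort effect at zero for the reference cohort. `model_tag = "APC"`
#' delegates to [fit_apc_two_step()]; `"saturated"` fits one parameter per
#' cell (deviance exactly zero), useful as a baseline.
#'
#' @param x a `lexis_table`.
#' @param model_tag one of `"AC"`, `"AP"`, `"APC"`, `"saturated"`.
#' @param reference_cohort central birth year of the cohort pinned at zero;
#'   default per [default_reference_cohort()].
#' @return an object of class `apc_fit` with components `effects` /
#'   `effect_sd` ([apc_effects()]; entries fixed by a constraint are exactly
#'   zero with sd 0, absent scales all zero), `deviance`
#'   (`2 * (loglik_saturated - loglik)`), `aic` (`-2 loglik + 2 df_model`),
#'   `df_model`, `converged`, `loglik`, per-cell `fitted` probabilities, and
#'   `flags` for degenerate (all-0 or all-n) levels, whose standard
#'   deviations are reported as `NA`.
#' @export
fit_binomial_glm <- function(x, model_tag = c("AC", "AP", "APC", "saturated"),
                             reference_cohort = NULL) {
  model_tag <- match.arg(model_tag)
  if (model_tag == "APC")
    return(fit_apc_two_step(x, reference_cohort))
  validate_lexis(x)
  df <- lexis_long(x)
  A <- nrow(x$y); P <- ncol(x$y); C <- A + P - 1
  clev <- levels(df$cohort)
  if (model_tag == "AC") {
    if (is.null(reference_cohort)) reference_cohort <- default_reference_cohort(x)
    if (!as.character(reference_cohort) %in% clev)
      stop("reference cohort ", reference_cohort, " not present in the table")
    df$cohort <- relevel(df$cohort, ref = as.character(reference_cohort))
  } else reference_cohort <- NA
  form <- switch(model_tag,
                 AC = cbind(y, n - y) ~ age + cohort,
                 AP = cbind(y, n - y) ~ age + period,
                 saturated = cbind(y, n - y) ~ age:period)
  flags <- character()
  for (fac in intersect(all.vars(form[[3]]), c("age", "period", "cohort"))) {
    bad <- degenerate_levels(df, fac)
    if (length(bad))
      flags <- c(flags, sprintf("degenerate %s level(s): %s", fac,
                                paste(bad, collapse = ",")))
  }
  if (length(flags))
    warning("separation risk: ", paste(flags, collapse = "; "))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  ag <- extract_factor(fit, "age", x$ages$central)
  pe <- extract_factor(fit, "period", x$periods$central)
  co <- extract_factor(fit, "cohort", clev)
  # blank out SDs of degenerate levels
  for (fac in c("age", "period", "cohort")) {
    bad <- degenerate_levels(df, fac)
    if (!length(bad)) next
    tgt <- switch(fac, age = "ag", period = "pe", cohort = "co")
    v <- get(tgt); v$sd[as.character(bad)] <- NA_real_; assign(tgt, v)
  }
  eff <- apc_effects(coef(fit)[["(Intercept)"]], ag$est, pe$est, co$est,
                     cohort_labels = as.numeric(clev),
                     reference_cohort = reference_cohort)
  esd <- apc_effects(sqrt(diag(vcov(fit)))[["(Intercept)"]], ag$sd, pe$sd,
                     co$sd, cohort_labels = as.numeric(clev),
                     reference_cohort = reference_cohort)
  new_apc_fit(model_tag, x, eff, esd,
              deviance = fit$deviance, aic = fit$aic,
              df_model = sum(!is.na(coef(fit))),
              converged = fit$converged,
              loglik = as.numeric(logLik(fit)),
              fitted = matrix(fitted(fit), A, P), flags = flags)
}

#' Fit the full APC model by the two-step procedure
#'
#' Step 1 fits the age-cohort (AC) model with the reference cohort pinned at
#' zero. Step 2 estimates the period effect from a second binomial GLM of
#' the same counts on the period factor alone, with the step-1 fit entering
#' as a fixed offset; the step-1 estimates are not revisited. This yields an
#' identified full APC fit in which the secular trend is carried by the
#' age/cohort scales, and standard deviations are available for every
#' effect.
#'
#' The offset enters by default as the step-1 linear predictor (logit of the
#' AC fitted probabilities), which keeps the binomial likelihood coherent on
#' the link scale. `offset_type = "log_fitted"` instead uses the log of the
#' AC fitted counts, the convention borrowed from Poisson rate modelling,
#' provided for comparison.
#'
#' @inheritParams fit_binomial_glm
#' @param offset_type `"logit"` (default) or `"log_fitted"`.
#' @return an `apc_fit` with `model_tag = "APC-two-step"`; `deviance` and
#'   `fitted` come from the step-2 model (the final fit), `df_model` counts
#'   the parameters estimated across both steps, and
#'   `aic = -2 loglik + 2 df_model`.
#' @export
fit_apc_two_step <- function(x, reference_cohort = NULL,
                             offset_type = c("logit", "log_fitted")) {
  offset_type <- match.arg(offset_type)
  step1 <- fit_binomial_glm(x, "AC", reference_cohort)
  df <- lexis_long(x)
  A <- nrow(x$y); P <- ncol(x$y)
  df$off <- if (offset_type == "logit") qlogis(as.vector(step1$fitted))
            else log(as.vector(step1$fitted) * df$n)
  step2 <- suppressWarnings(
    glm(cbind(y, n - y) ~ period, offset = off, family = binomial(), data = df))
  pe <- extract_factor(step2, "period", x$periods$central)
  e1 <- step1$effects; s1 <- step1$effect_sd
  b0 <- coef(step2)[["(Intercept)"]]
  eff <- apc_effects(e1$mu + b0, e1$age, pe$est, e1$cohort,
                     cohort_labels = e1$cohort_labels,
                     reference_cohort = e1$reference_cohort)
  esd <- apc_effects(sqrt(s1$mu^2 + diag(vcov(step2))[["(Intercept)"]]),
                     s1$age, pe$sd, s1$cohort,
                     cohort_labels = e1$cohort_labels,
                     reference_cohort = e1$reference_cohort)
  df_model <- step1$df_model + sum(!is.na(coef(step2)))
  ll <- as.numeric(logLik(step2))
  new_apc_fit("APC-two-step", x, eff, esd,
              deviance = step2$deviance,
              aic = -2 * ll + 2 * df_model,
              df_model = df_model,
              converged = step1$converged && step2$converged,
              loglik = ll,
              fitted = matrix(fitted(step2), A, P),
              flags = step1$flags)
}

#' Compare the APC, AP and AC models on one table
#'
#' Fits all three models and tabulates AIC, deviance and the change in
#' deviance relative to the full APC fit. Both submodels are nested in the
#' APC model, so their deviance change is non-negative (up to the numerical
#' tolerance of the two-step fit) and a large `delta_dev` marks the dropped
#' scale as important.
#'
#' @inheritParams fit_apc_two_step
#' @return data frame with columns `model` (`"APC"`, `"AP"`, `"AC"`),
#'   `aic`, `deviance`, `delta_dev` (`NA` for the APC row), plus attribute
#'   `fits` holding the three `apc_fit` objects.
#' @export
compare_models <- function(x, reference_cohort = NULL,
                           offset_type = c("logit", "log_fitted")) {
  apc <- fit_apc_two_step(x, reference_cohort, offset_type)
  ap <- fit_binomial_glm(x, "AP")
  ac <- fit_binomial_glm(x, "AC", reference_cohort)
  out <- data.frame(
    model = c("APC", "AP", "AC"),
    aic = c(apc$aic, ap$aic, ac$aic),
    deviance = c(apc$deviance, ap$deviance, ac$deviance),
    delta_dev = c(NA, ap$deviance - apc$deviance, ac$deviance - apc$deviance))
  attr(out, "fits") <- list(APC = apc, AP = ap, AC = ac)
  out
}
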
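# fixtures built in code: random valid Lexis tables and tiny grids

random_lexis <- function(seed, A = NULL, P = NULL, n_max = 500) {
  set.seed(seed)
  if (is.null(A)) A <- sample(1:12, 1)
  if (is.null(P)) P <- sample(1:8, 1)
  n <- matrix(sample(5:n_max, A * P, replace = TRUE), A, P)
  p <- matrix(runif(A * P, 0.05, 0.6), A, P)
  y <- matrix(rbinom(A * P, as.vector(n), as.vector(p)), A, P)
  lexis_table(y, n,
              age_lower = seq(25, by = 5, length.out = A),
              period_start = seq(1980, by = 5, length.out = P),
              gender = sample(c("male", "female"), 1))
}

# deterministic tiny grid for exact checks
toy_table <- function(A = 3, P = 2, n = 40) {
  y <- matrix(seq(4, by = 3, length.out = A * P), A, P)
  lexis_table(y, matrix(n, A, P),
              age_lower = seq(25, by = 5, length.out = A),
              period_start = seq(1980, by = 5, length.out = P))
}

# independent term-by-term oracle for the log unnormalised posterior,
# written against the model definition, not the package internals
oracle_log_posterior <- function(eff, tau, tab, priors) {
  A <- nrow(tab$y); P <- ncol(tab$y)
  ll <- 0
  for (a in seq_len(A)) for (p in seq_len(P)) {
    eta <- eff$mu + eff$age[a] + eff$period[p] + eff$cohort[p - a + A]
    pr <- 1 / (1 + exp(-eta))
    ll <- ll + lchoose(tab$n[a, p], tab$y[a, p]) +
      tab$y[a, p] * log(pr) + (tab$n[a, p] - tab$y[a, p]) * log(1 - pr)
  }
  rw <- function(v, tau) {
    d <- diff(v)
    sum(-0.5 * log(2 * pi) + 0.5 * log(tau) - 0.5 * tau * d^2)
  }
  ll + rw(eff$age, tau[1]) + rw(eff$period, tau[2]) + rw(eff$cohort, tau[3]) +
    sum(priors$shape * log(priors$rate) - lgamma(priors$shape) +
        (priors$shape - 1) * log(tau) - priors$rate * tau) +
    (-0.5 * log(2 * pi * priors$mu_var) -
       0.5 * (eff$mu - priors$mu_mean)^2 / priors$mu_var)
}

# brute-force ML oracle for AC / AP fits on small grids: direct optimisation
# of the binomial log-likelihood over the corner-constrained parameters
oracle_loglik <- function(tab, model = c("AC", "AP"), reference_cohort = NULL) {
  model <- match.arg(model)
  A <- nrow(tab$y); P <- ncol(tab$y); C <- A + P - 1
  cpos <- outer(seq_len(A), seq_len(P), function(a, p) p - a + A)
  coh <- sort(unique(as.vector(cohort_grid(tab))))
  ref_pos <- if (model == "AC") {
    if (is.null(reference_cohort)) reference_cohort <- default_reference_cohort(tab)
    match(reference_cohort, coh)
  } else NA
  build_eta <- function(par) {
    mu <- par[1]
    alpha <- c(0, par[seq_len(A - 1) + 1])
    k <- A
    if (model == "AP") {
      beta <- c(0, par[seq_len(P - 1) + k]); gam <- rep(0, C)
    } else {
      beta <- rep(0, P)
      gam <- numeric(C); gam[-ref_pos] <- par[seq_len(C - 1) + k]
    }
    mu + outer(alpha, beta, "+") + matrix(gam[cpos], A, P)
  }
  npar <- 1 + (A - 1) + if (model == "AP") P - 1 else C - 1
  nll <- function(par) {
    eta <- build_eta(par)
    -sum(dbinom(tab$y, tab$n, plogis(eta), log = TRUE))
  }
  fit <- optim(rep(0, npar), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  -fit$value
}
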
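Package: apcprev
Title: Age-Period-Cohort Models for Smoking-Cessation Prevalence Trends and
    Projections
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing prevalence tables on the Lexis grid with
    age-period-cohort (APC) models, motivated by trends in former-smoker
    prevalence from repeated cross-sectional health surveys. Provides a
    Lexis-table data structure with cohort indexing and age-cumulated
    prevalence, a synthetic-data generator with identifiability-normalised
    ground truth, classical binomial APC fitting via a two-step procedure
    that resolves the age-period-cohort identifiability problem by
    attributing the secular trend to the cohort effect, a Bayesian APC model
    with first-order random-walk smoothing priors fitted by
    Metropolis-within-Gibbs MCMC (with Geweke convergence diagnostics and
    prior-sensitivity scanning), stochastic projection of future prevalence
    with credible intervals, and downstream linear extrapolation of smoker
    prevalence to an estimated "end of smoking" year.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
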
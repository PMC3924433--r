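#' @useDynLib apcprev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Lexis-grid data model: prevalence tables by 5-year age band x 5-year period,
# with birth cohorts induced along the diagonals (cohort = period - age).
# ---------------------------------------------------------------------------

BAND_WIDTH <- 5L

band_frame <- function(lower) {
  lower <- as.integer(lower)
  data.frame(lower = lower, upper = lower + BAND_WIDTH - 1L,
             central = lower + (BAND_WIDTH - 1) / 2)
}

#' Construct a Lexis prevalence table
#'
#' A Lexis table holds former-smoker counts `y` and respondent counts `n` on
#' a grid of contiguous 5-year age bands by contiguous 5-year calendar
#' periods, for one gender. Birth cohorts are induced on the diagonals via
#' `cohort = period - age` and labelled by central birth year.
#'
#' @param y integer matrix (A x P) of event counts (e.g. former smokers).
#' @param n integer matrix (A x P) of respondents per cell; all positive.
#' @param age_lower integer vector of length A: lower bound of each 5-year
#'   age band (e.g. `seq(25, 80, by = 5)`).
#' @param period_start integer vector of length P: first calendar year of
#'   each 5-year period (e.g. `seq(1980, 2005, by = 5)`).
#' @param gender label for the stratum, e.g. `"male"`.
#' @return an object of class `lexis_table` with components `gender`,
#'   `ages`, `periods` (data frames with `lower`/`start`, `upper`/`end`,
#'   `central`), and matrices `y`, `n`.
#' @examples
#' tab <- lexis_table(matrix(5, 2, 2), matrix(50, 2, 2),
#'                    age_lower = c(25, 30), period_start = c(1980, 1985))
#' prevalence(tab)
#' @export
lexis_table <- function(y, n, age_lower = seq(25, by = 5, length.out = nrow(y)),
                        period_start = seq(1980, by = 5, length.out = ncol(y)),
                        gender = "unspecified") {
  y <- as.matrix(y); n <- as.matrix(n)
  ages <- band_frame(age_lower)
  periods <- band_frame(period_start)
  names(periods) <- c("start", "end", "central")
  obj <- structure(list(gender = as.character(gender), ages = ages,
                        periods = periods, y = y, n = n),
                   class = "lexis_table")
  validate_lexis(obj)
  obj
}

#' Validate a Lexis table
#'
#' Checks the structural invariants: matching dimensions, 5-year contiguous
#' strictly increasing bands, age bands within 25--84, integer counts with
#' `0 <= y <= n` and `n > 0` cellwise. Violations raise an error naming the
#' offending cell or band.
#'
#' @param x a `lexis_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_lexis <- function(x) {
  stopifnot(inherits(x, "lexis_table"))
  A <- nrow(x$y); P <- ncol(x$y)
  if (!all(dim(x$n) == c(A, P)))
    stop("y and n must have identical dimensions")
  if (nrow(x$ages) != A || nrow(x$periods) != P)
    stop("band metadata does not match count matrix dimensions")
  chk_bands <- function(lo, what) {
    if (any(diff(lo) != BAND_WIDTH))
      stop(sprintf("%s bands must be contiguous 5-year bands in increasing order", what))
  }
  chk_bands(x$ages$lower, "age")
  chk_bands(x$periods$start, "period")
  if (any(x$ages$lower < 25) || any(x$ages$upper > 84))
    stop("age bands must lie within 25-84 years")
  bad <- which(x$n <= 0 | x$n != round(x$n), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid respondent count in cell age %d-%d, period %d-%d",
                 x$ages$lower[bad[1, 1]], x$ages$upper[bad[1, 1]],
                 x$periods$start[bad[1, 2]], x$periods$end[bad[1, 2]]))
  bad <- which(x$y < 0 | x$y > x$n | x$y != round(x$y), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count y (must satisfy 0 <= y <= n) in cell age %d-%d, period %d-%d",
                 x$ages$lower[bad[1, 1]], x$ages$upper[bad[1, 1]],
                 x$periods$start[bad[1, 2]], x$periods$end[bad[1, 2]]))
  invisible(x)
}

#' @export
print.lexis_table <- function(x, ...) {
  cat(sprintf("Lexis table (%s): %d age bands (%d-%d) x %d periods (%d-%d)\n",
              x$gender, nrow(x$y), min(x$ages$lower), max(x$ages$upper),
              ncol(x$y), min(x$periods$start), max(x$periods$end)))
  cat(sprintf("  %d cells, %s respondents, crude prevalence %.3f\n",
              length(x$y), format(sum(x$n), big.mark = ","),
              sum(x$y) / sum(x$n)))
  invisible(x)
}

#' @export
dim.lexis_table <- function(x) dim(x$y)

#' Observed per-cell prevalence
#' @param x a `lexis_table`.
#' @return matrix `y / n`.
#' @export
prevalence <- function(x) {
  validate_lexis(x)
  x$y / x$n
}

#' Central birth year of the cohort through a Lexis cell
#'
#' Cohorts are labelled by central year of birth using
#' `cohort = period - age` applied to band midpoints, so the 25-29 band in
#' 2005-2009 maps to the 1980 cohort and the 80-84 band in 1980-1984 to 1900.
#'
#' @param age_central central year of the age band (e.g. 27 for 25-29).
#' @param period_central central calendar year of the period
#'   (e.g. 2007 for 2005-2009).
#' @return central birth year(s), `period_central - age_central`.
#' @examples
#' cohort_index(27, 2007)  # 1980
#' cohort_index(82, 1982)  # 1900
#' @export
cohort_index <- function(age_central, period_central) {
  period_central - age_central
}

#' Matrix of cohort labels for every cell of a table
#' @param x a `lexis_table`.
#' @return A x P matrix of central birth years.
#' @export
cohort_grid <- function(x) {
  outer(x$ages$central, x$periods$central, function(a, p) cohort_index(a, p))
}

#' Enumerate the cohorts of a Lexis table
#'
#' An A x P grid of 5-year bands induces `A + P - 1` overlapping 5-year
#' cohorts along the diagonals; corner cohorts are observed in a single cell
#' and central ones in up to `min(A, P)` cells, so their effects are
#' estimated with unequal precision.
#'
#' @param x a `lexis_table`.
#' @return data frame with `cohort` (central birth year, ascending) and
#'   `cells` (number of grid cells observing that cohort).
#' @examples
#' tab <- lexis_table(matrix(1, 12, 6), matrix(10, 12, 6))
#' nrow(enumerate_cohorts(tab))  # 17
#' @export
enumerate_cohorts <- function(x) {
  validate_lexis(x)
  g <- cohort_grid(x)
  tb <- table(g)
  data.frame(cohort = as.numeric(names(tb)), cells = as.integer(tb))
}

# 1-based cohort position (1 = oldest cohort) for each cell; used by fitters.
cohort_pos <- function(x) {
  g <- cohort_grid(x)
  matrix(match(g, sort(unique(as.vector(g)))), nrow(g), ncol(g))
}

#' Restrict a Lexis table to a window of periods
#'
#' Keeps the age bands and drops periods, e.g. to re-run an analysis on the
#' most recent survey window only (the induced cohort set shrinks
#' accordingly).
#'
#' @param x a `lexis_table`.
#' @param period_start starting years of the periods to keep (must be
#'   contiguous).
#' @return a `lexis_table` over the selected periods.
#' @export
lexis_subset <- function(x, period_start) {
  validate_lexis(x)
  keep <- match(period_start, x$periods$start)
  if (anyNA(keep)) stop("period(s) not present in the table")
  lexis_table(x$y[, keep, drop = FALSE], x$n[, keep, drop = FALSE],
              age_lower = x$ages$lower,
              period_start = x$periods$start[keep], gender = x$gender)
}

#' Read a Lexis table from CSV
#'
#' Expects a comma-delimited UTF-8 file with header columns `gender`,
#' `age_lower`, `age_upper`, `period_start`, `period_end`, `y`, `n` and one
#' row per cell. The grid must be complete; structural violations (missing
#' cells, `y > n`, non-contiguous bands) raise an error naming the offender.
#'
#' @param path file path.
#' @return a `lexis_table`.
#' @seealso [write_lexis()] for the inverse; round-trips are exact.
#' @export
read_lexis <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "age_lower", "age_upper", "period_start", "period_end", "y", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(df$gender)) != 1)
    stop("a Lexis CSV must contain exactly one gender; found: ",
         paste(unique(df$gender), collapse = ", "))
  age_lower <- sort(unique(df$age_lower))
  period_start <- sort(unique(df$period_start))
  A <- length(age_lower); P <- length(period_start)
  if (nrow(df) != A * P)
    stop(sprintf("incomplete grid: expected %d cells (%d ages x %d periods), found %d rows",
                 A * P, A, P, nrow(df)))
  y <- matrix(NA_real_, A, P); n <- matrix(NA_real_, A, P)
  ai <- match(df$age_lower, age_lower)
  pi_ <- match(df$period_start, period_start)
  key <- (pi_ - 1) * A + ai
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate cell: age %d, period %d", d$age_lower, d$period_start))
  }
  y[cbind(ai, pi_)] <- df$y
  n[cbind(ai, pi_)] <- df$n
  lexis_table(y, n, age_lower = age_lower, period_start = period_start,
              gender = df$gender[1])
}

#' Write a Lexis table to CSV
#' @param x a `lexis_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexis <- function(x, path) {
  validate_lexis(x)
  A <- nrow(x$y); P <- ncol(x$y)
  df <- data.frame(
    gender = x$gender,
    age_lower = rep(x$ages$lower, times = P),
    age_upper = rep(x$ages$upper, times = P),
    period_start = rep(x$periods$start, each = A),
    period_end = rep(x$periods$end, each = A),
    y = as.vector(x$y),
    n = as.vector(x$n))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age-cumulated prevalence per period
#'
#' Collapses per-cell prevalence over the age bands within each period into
#' one scalar per period, as a weighted mean `sum(w_a * p_ap) / sum(w_a)`.
#' The default weights are the respondent counts of each age band within the
#' period (survey-consistent crude prevalence); `"equal"` gives the
#' unweighted mean over age bands, and a numeric vector of length A applies
#' fixed weights to every period.
#'
#' @param x a `lexis_table` supplying the default weights (and, if `probs`
#'   is `NULL`, the observed prevalence `y/n`).
#' @param probs optional A x P matrix of cell probabilities to cumulate
#'   instead of the observed prevalence (e.g. fitted values or a posterior
#'   draw).
#' @param weights `"respondents"` (default), `"equal"`, or a non-negative
#'   numeric vector of length A (not all zero).
#' @return named numeric vector, one prevalence per period, each bounded by
#'   the min and max cell prevalence of its period.
#' @examples
#' tab <- lexis_table(matrix(c(1, 3), 2, 2) * 10, matrix(100, 2, 2))
#' cumulate_prevalence(tab)                     # 0.2 per period
#' cumulate_prevalence(tab, weights = c(1, 3))  # 0.25
#' @export
cumulate_prevalence <- function(x, probs = NULL, weights = "respondents") {
  validate_lexis(x)
  p <- if (is.null(probs)) prevalence(x) else as.matrix(probs)
  A <- nrow(x$y); P <- ncol(p)
  if (nrow(p) != A) stop("probs must have one row per age band")
  if (is.character(weights)) {
    weights <- match.arg(weights, c("respondents", "equal"))
    w <- if (weights == "equal") matrix(1, A, P) else {
      if (ncol(x$n) == P) x$n else matrix(x$n[, ncol(x$n)], A, P)
    }
  } else {
    if (length(weights) != A || any(weights < 0))
      stop("numeric weights must be non-negative and of length A")
    if (sum(weights) == 0) stop("weights must not be all zero")
    w <- matrix(weights, A, P)
  }
  out <- colSums(w * p) / colSums(w)
  names(out) <- if (P == ncol(x$y)) x$periods$central else NULL
  out
}
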
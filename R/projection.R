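# ---------------------------------------------------------------------------
# Downstream series arithmetic: the population splits into smokers, former
# smokers and never ("non") smokers, so smoker prevalence follows as the
# complement of the other two; its linear tail extrapolation dates the
# "end of smoking".
# ---------------------------------------------------------------------------

#' A prevalence time series in percent
#'
#' @param years strictly increasing calendar years.
#' @param values prevalence in percent per year, all >= 0.
#' @param gender stratum label.
#' @param kind one of `"smoker"`, `"non_smoker"`, `"former"`.
#' @return object of class `prev_series` (a data frame with `year`,
#'   `value` and the labels as attributes).
#' @export
prevalence_series <- function(years, values, gender = "unspecified",
                              kind = c("smoker", "non_smoker", "former")) {
  kind <- match.arg(kind)
  if (length(years) != length(values)) stop("years and values must align")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (any(values < 0)) stop("prevalence values must be >= 0")
  structure(data.frame(year = as.numeric(years), value = as.numeric(values)),
            gender = gender, kind = kind,
            class = c("prev_series", "data.frame"))
}

#' Least-squares linear projection of a prevalence series
#'
#' Fits the ordinary least-squares line through the anchor points and
#' evaluates it at the target years, clamping to [0, 100] percent. With two
#' anchors the line interpolates them exactly.
#'
#' @param anchors data frame (or `prev_series`) with columns `year`,
#'   `value`; at least two rows with distinct years.
#' @param target_years years at which to evaluate the line.
#' @param gender,kind labels for the result.
#' @return a `prev_series` over `target_years` with attribute `clamped`
#'   (logical per year: value was cut at 0 or 100).
#' @export
linear_projection <- function(anchors, target_years, gender = "unspecified",
                              kind = "non_smoker") {
  if (nrow(anchors) < 2) stop("need >= 2 anchor points")
  if (length(unique(anchors$year)) < 2) stop("anchor years must not be identical")
  fit <- lm(value ~ year, data = anchors)
  raw <- unname(predict(fit, newdata = data.frame(year = target_years)))
  val <- pmin(pmax(raw, 0), 100)
  out <- prevalence_series(target_years, val, gender = gender, kind = kind)
  attr(out, "clamped") <- raw != val
  attr(out, "raw") <- raw
  out
}

#' Derive the smoker series as the complement of former and non-smokers
#'
#' The adult population is composed of current smokers, former smokers and
#' never smokers, so `smoker% = 100 - former% - non_smoker%`. If the
#' non-smoker series does not cover the former-smoker years it is extended
#' by [linear_projection()] from its own points (>= 2 required). Negative
#' complements are clamped at zero at presentation; the raw values are kept
#' in the `raw` attribute and clamp events flagged.
#'
#' @param former a `prev_series` of former-smoker prevalence (percent).
#' @param non_smoker a `prev_series` of never-smoker prevalence; same years
#'   as `former`, or fewer (then linearly extended).
#' @return a `prev_series` of kind `"smoker"` with attributes `raw`
#'   (pre-clamp values, summing with the inputs to exactly 100) and
#'   `clamped`.
#' @export
assemble_smoker_series <- function(former, non_smoker) {
  if (any(former$value < 0) || any(non_smoker$value < 0))
    stop("input prevalences must be >= 0")
  if (!all(former$year %in% non_smoker$year)) {
    non_smoker <- linear_projection(non_smoker, former$year,
                                    gender = attr(former, "gender"),
                                    kind = "non_smoker")
  } else {
    non_smoker <- non_smoker[match(former$year, non_smoker$year), ]
  }
  raw <- 100 - former$value - non_smoker$value
  val <- pmax(raw, 0)
  out <- prevalence_series(former$year, val,
                           gender = attr(former, "gender"), kind = "smoker")
  attr(out, "raw") <- raw
  attr(out, "clamped") <- raw < 0
  if (any(raw < 0))
    message(sum(raw < 0), " year(s) clamped at 0% smoker prevalence")
  out
}

#' Date the "end of smoking" by tail extrapolation
#'
#' Takes the last two strictly positive tabulated values of a smoker
#' prevalence series, extends their straight line to its zero crossing, and
#' rounds the crossing year to the nearest multiple of `rounding` (an
#' "around year X" statement). Trailing exact zeros are ignored: the
#' extrapolated crossing of the last positive segment governs. If only one
#' positive value remains before a tabulated zero, the segment from that
#' value to the first zero is used (crossing at the zero year when the next
#' entry is zero). The reported year never precedes the last positive year.
#'
#' @param series a `prev_series` (kind `"smoker"`), values in percent.
#' @param rounding report the crossing to the nearest multiple of this many
#'   years (default 5, the tabulation step).
#' @return object of class `end_of_smoking`: `crossing_year_raw`
#'   (continuous), `reported_year` (rounded), `segment` (the two anchor
#'   points used).
#' @examples
#' s <- prevalence_series(c(2050, 2055), c(2, 0), kind = "smoker")
#' end_of_smoking(s)$reported_year  # 2055
#' @export
end_of_smoking <- function(series, rounding = 5) {
  v <- series$value; yr <- series$year
  pos <- which(v > 0)
  if (length(pos) == 0) stop("no finite crossing: series has no positive values")
  if (length(pos) >= 2) {
    i <- pos[length(pos) - 1]; j <- pos[length(pos)]
  } else {
    j0 <- pos[length(pos)]
    zer <- which(v == 0 & yr > yr[j0])
    if (!length(zer)) stop("no finite crossing: need >= 2 positive values or a trailing zero")
    i <- j0; j <- zer[1]
  }
  t1 <- yr[i]; v1 <- v[i]; t2 <- yr[j]; v2 <- v[j]
  if (v2 >= v1) stop("no finite crossing: series tail is not decreasing")
  slope <- (v2 - v1) / (t2 - t1)
  crossing <- t2 - v2 / slope
  reported <- round(crossing / rounding) * rounding
  last_pos <- yr[pos[length(pos)]]
  if (reported < last_pos) reported <- ceiling(crossing / rounding) * rounding
  structure(list(crossing_year_raw = crossing, reported_year = reported,
                 segment = data.frame(year = c(t1, t2), value = c(v1, v2)),
                 rounding = rounding),
            class = "end_of_smoking")
}

#' @export
print.end_of_smoking <- function(x, ...) {
  cat(sprintf("End of smoking: ~%d (linear crossing at %.1f, tail %g%% in %d -> %g%% in %d)\n",
              x$reported_year, x$crossing_year_raw,
              x$segment$value[1], x$segment$year[1],
              x$segment$value[2], x$segment$year[2]))
  invisible(x)
}

#' Read/write a prevalence series as 2-column CSV (`year,value`)
#' @param path file path.
#' @param gender,kind labels attached to the series on reading.
#' @return a `prev_series`.
#' @export
read_series <- function(path, gender = "unspecified", kind = "smoker") {
  df <- read.csv(path)
  if (!all(c("year", "value") %in% names(df)))
    stop("series CSV needs columns year,value")
  prevalence_series(df$year, df$value, gender = gender, kind = kind)
}

#' @rdname read_series
#' @param series a `prev_series` to write.
#' @export
write_series <- function(series, path) {
  write.csv(data.frame(year = series$year, value = series$value), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-gender projection table (`year,male,female` CSV)
#'
#' The packaged example `smokers_projection_italy.csv` holds projected
#' Italian smoker prevalence (%) for 2012-2062 in 5-year steps; its tail
#' extrapolation dates the end of smoking around 2060 (men) and 2055
#' (women).
#'
#' @param path CSV with columns `year`, `male`, `female`.
#' @return named list of two `prev_series` (`male`, `female`).
#' @examples
#' tab <- read_projection_table(
#'   system.file("extdata", "smokers_projection_italy.csv", package = "apcprev"))
#' end_of_smoking(tab$male)$reported_year
#' @export
read_projection_table <- function(path) {
  df <- read.csv(path)
  if (!all(c("year", "male", "female") %in% names(df)))
    stop("projection table needs columns year,male,female")
  list(male = prevalence_series(df$year, df$male, "male", "smoker"),
       female = prevalence_series(df$year, df$female, "female", "smoker"))
}
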
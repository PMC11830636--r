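# Hip-fracture burden projection.
#
# Applies stable age/sex-specific incidence to population pyramids: expected
# annual fractures = sum over bands of rate/100,000 x head count (a head
# count approximates person-years for an annual snapshot). Demographic
# ageing alone then drives the projected burden.

#' Read population pyramids from CSV
#'
#' Columns `year, sex, age_low, age_high, count`; an empty `age_high` marks
#' the open-ended top band.
#'
#' @param path CSV file path.
#' @return validated data.frame of pyramids (possibly several years).
#' @export
read_population_pyramids <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  population_pyramids(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a population-pyramid data.frame
#'
#' @param data data.frame with columns `year`, `sex`, `age_low`, `age_high`
#'   (`NA` = open-ended), `count` (head counts, non-negative).
#' @return the validated data.frame, sorted by year, sex, age.
#' @export
population_pyramids <- function(data) {
  req <- c("year", "sex", "age_low", "age_high", "count")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("pyramid is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(year = as.integer(data$year),
                   sex = as.character(data$sex),
                   age_low = as.numeric(data$age_low),
                   age_high = suppressWarnings(as.numeric(data$age_high)),
                   count = as.numeric(data$count),
                   stringsAsFactors = FALSE)
  bad <- which(!df$sex %in% SEXES)
  if (length(bad)) {
    stop("unknown sex code in pyramid row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad)) {
    stop("negative or missing count in pyramid row(s) ",
         paste(bad, collapse = ", "))
  }
  df <- df[order(df$year, df$sex, df$age_low), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Expected annual fracture counts for one pyramid
#'
#' Sums `rate / 100,000 * count` over all bands at or above `min_age`,
#' separately by sex. Each pyramid band at or above `min_age` must match an
#' incidence band exactly (same `sex`, `age_low`, `age_high`); `min_age`
#' itself must sit on a band edge.
#'
#' @param incidence a [rate_table()] (typically hip-fracture incidence).
#' @param pyramid one year's pyramid rows ([population_pyramids()] format).
#' @param min_age lower age cut (default 50).
#' @return named numeric vector `c(F = , M = )` of expected fracture counts.
#' @export
expected_fractures <- function(incidence, pyramid, min_age = 50) {
  stopifnot(inherits(incidence, "rate_table"))
  pyramid <- population_pyramids(pyramid)
  if (length(unique(pyramid$year)) > 1) {
    stop("expected_fractures takes a single year; use project_series")
  }
  if (!min_age %in% pyramid$age_low) {
    stop("min_age ", min_age, " does not align with a pyramid band edge")
  }
  sel <- pyramid[pyramid$age_low >= min_age, , drop = FALSE]
  m <- match(band_key(sel), band_key(incidence))
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stop("pyramid band (", sel$sex[i], ", ", sel$age_low[i],
         ") has no matching incidence band")
  }
  events <- incidence$rate[m] / 1e5 * sel$count
  out <- c(F = 0, M = 0)
  agg <- tapply(events, sel$sex, sum)
  out[names(agg)] <- agg
  out
}

#' Project the annual burden over calendar years
#'
#' Applies the (stable) incidence to each year's pyramid and expresses every
#' year's total relative to the base year as `increase_index = 100 x
#' total / total(base)` — a ratio index (base year = 100), the convention
#' used in published projection tables.
#'
#' @inheritParams expected_fractures
#' @param pyramids multi-year pyramid data.frame.
#' @param base_year calendar year the index is anchored to (must be present).
#' @return a `burden_series` data.frame: `year`, `men`, `women`, `total`
#'   (full precision) and `increase_index` (rounded half-up to integer).
#' @export
project_series <- function(incidence, pyramids, base_year, min_age = 50) {
  pyramids <- population_pyramids(pyramids)
  years <- sort(unique(pyramids$year))
  if (!base_year %in% years) {
    stop("base_year ", base_year, " not present among the pyramids")
  }
  per_year <- t(vapply(years, function(y) {
    expected_fractures(incidence, pyramids[pyramids$year == y, , drop = FALSE],
                       min_age = min_age)
  }, c(F = 0, M = 0)))
  total <- per_year[, "F"] + per_year[, "M"]
  base_total <- total[years == base_year]
  if (base_total <= 0) stop("zero expected fractures in the base year")
  structure(data.frame(year = years,
                       men = per_year[, "M"],
                       women = per_year[, "F"],
                       total = total,
                       increase_index = round_half_up(100 * total / base_total,
                                                      0)),
            class = c("burden_series", "data.frame"),
            base_year = base_year)
}

#' @export
print.burden_series <- function(x, ...) {
  y <- as.data.frame(x)
  y$men <- round_half_up(y$men, 0)
  y$women <- round_half_up(y$women, 0)
  y$total <- round_half_up(y$total, 0)
  cat("Projected annual hip fractures (base year ", attr(x, "base_year"),
      " = index 100):\n", sep = "")
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Fold increase in the annual burden between two years
#'
#' @param series a [project_series()] result.
#' @param from_year,to_year calendar years present in the series.
#' @return `total(to) / total(from)`, rounded half-up to one decimal.
#' @export
fold_increase <- function(series, from_year, to_year) {
  stopifnot(inherits(series, "burden_series"))
  if (!all(c(from_year, to_year) %in% series$year)) {
    stop("both years must be present in the series")
  }
  from <- series$total[series$year == from_year]
  if (from <= 0) stop("zero total in the base year")
  round_half_up(series$total[series$year == to_year] / from, 1)
}
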
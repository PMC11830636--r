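# Age/sex hazard tables.
#
# Incidence and mortality enter the model as rates per 100,000 person-years on
# 5-year age bands, the format national statistics and fracture registers
# publish. Bands are half-open [age_low, age_high); the last band may be
# open-ended (age_high = NA, meaning "and above"). Rates are stored exactly as
# read and converted to per-person-year hazards only in hazard_at(), keeping
# file round-trips lossless.

RATE_OUTCOMES <- c("hip_fracture", "mof", "death")
SEXES <- c("F", "M")

#' Construct a validated age/sex rate table
#'
#' An `rate_table` holds age- and sex-specific event rates per 100,000
#' person-years on contiguous half-open age bands, identical across the two
#' sexes. It is the common container for hip-fracture incidence, imputed
#' major-osteoporotic-fracture (MOF) incidence and all-cause mortality.
#'
#' @param data data.frame with columns `sex` (`"F"`/`"M"`), `age_low`,
#'   `age_high` (years; `NA` marks the final open-ended band) and `rate`
#'   (events per 100,000 person-years, non-negative).
#' @param outcome what the rates count: `"hip_fracture"`, `"mof"` or
#'   `"death"`.
#' @param source_label free-text provenance (country, period, register).
#' @return a `rate_table`: the normalised data.frame (sorted by sex then age)
#'   with `outcome` and `source_label` attributes.
#' @seealso [read_rate_table()], [hazard_at()], [impute_mof_incidence()]
#' @export
rate_table <- function(data, outcome = c("hip_fracture", "mof", "death"),
                       source_label = "") {
  outcome <- match.arg(outcome)
  req <- c("sex", "age_low", "age_high", "rate")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(
    sex = as.character(data$sex),
    age_low = as.numeric(data$age_low),
    age_high = suppressWarnings(as.numeric(data$age_high)),
    rate = as.numeric(data$rate),
    stringsAsFactors = FALSE
  )
  bad <- which(!df$sex %in% SEXES)
  if (length(bad)) {
    stop("unknown sex code in row(s) ", paste(bad, collapse = ", "),
         "; expected F or M")
  }
  if (!all(SEXES %in% df$sex)) {
    stop("both sexes (F and M) must be present; found only ",
         paste(unique(df$sex), collapse = ", "))
  }
  bad <- which(is.na(df$rate) | df$rate < 0)
  if (length(bad)) {
    stop("negative or missing rate in row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(is.na(df$age_low))
  if (length(bad)) {
    stop("missing age_low in row(s) ", paste(bad, collapse = ", "))
  }
  df <- df[order(df$sex, df$age_low), , drop = FALSE]
  rownames(df) <- NULL
  for (s in SEXES) {
    b <- df[df$sex == s, , drop = FALSE]
    validate_bands(b, s)
  }
  bf <- df[df$sex == "F", c("age_low", "age_high")]
  bm <- df[df$sex == "M", c("age_low", "age_high")]
  if (nrow(bf) != nrow(bm) ||
      !isTRUE(all.equal(bf$age_low, bm$age_low)) ||
      !identical(is.na(bf$age_high), is.na(bm$age_high)) ||
      !isTRUE(all.equal(bf$age_high[!is.na(bf$age_high)],
                        bm$age_high[!is.na(bm$age_high)]))) {
    stop("band structure differs between the sexes")
  }
  structure(df, class = c("rate_table", "data.frame"),
            outcome = outcome, source_label = source_label)
}

validate_bands <- function(b, sex) {
  open <- which(is.na(b$age_high))
  if (length(open) > 1 || (length(open) == 1 && open != nrow(b))) {
    stop("only the last band may be open-ended (sex ", sex, ")")
  }
  closed <- b[!is.na(b$age_high), , drop = FALSE]
  bad <- which(closed$age_high <= closed$age_low)
  if (length(bad)) {
    stop("empty or inverted band [", closed$age_low[bad[1]], ", ",
         closed$age_high[bad[1]], ") for sex ", sex)
  }
  if (nrow(b) > 1) {
    hi <- b$age_high[-nrow(b)]
    lo <- b$age_low[-1]
    i <- which(lo < hi)
    if (length(i)) {
      stop("overlapping bands for sex ", sex, ": [", b$age_low[i[1]], ", ",
           hi[i[1]], ") and [", lo[i[1]], ", ", b$age_high[i[1] + 1], ")")
    }
    i <- which(lo > hi)
    if (length(i)) {
      stop("gap between bands for sex ", sex, " at age ", hi[i[1]])
    }
  }
  invisible(TRUE)
}

#' Read a rate table from delimited text
#'
#' Expects CSV with columns `sex,age_low,age_high,rate`; an empty `age_high`
#' marks the final open-ended band. Validation failures name the offending
#' rows.
#'
#' @param path file path.
#' @inheritParams rate_table
#' @return a validated [rate_table()].
#' @export
read_rate_table <- function(path, outcome = c("hip_fracture", "mof", "death"),
                            source_label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rate_table(df, outcome = outcome, source_label = source_label)
}

#' Write a rate table as CSV
#'
#' Inverse of [read_rate_table()]: the open-ended band is written with an
#' empty `age_high`. Writing a freshly read table reproduces the normalised
#' file byte for byte.
#'
#' @param x a `rate_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  utils::write.csv(as.data.frame(x)[, c("sex", "age_low", "age_high", "rate")],
                   path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Age/sex rate table -", attr(x, "outcome"),
      "(per 100,000 person-years)\n")
  if (nzchar(attr(x, "source_label"))) {
    cat("  source:", attr(x, "source_label"), "\n")
  }
  cat("  bands:", nrow(x) / 2, "per sex, ages", min(x$age_low), "to",
      max(x$age_low), if (anyNA(x$age_high)) "+ (open-ended)" else "", "\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Midpoints of the age bands; the open-ended top band is assigned the width
# of the preceding band (5 years if it is the only band).
band_midpoints <- function(b) {
  hi <- b$age_high
  n <- nrow(b)
  if (is.na(hi[n])) {
    w <- if (n > 1) b$age_high[n - 1] - b$age_low[n - 1] else 5
    hi[n] <- b$age_low[n] + w
  }
  (b$age_low + hi) / 2
}

#' Per-year hazard at an exact age
#'
#' Converts the banded rates to a per-person-year hazard at arbitrary ages.
#' `"step"` returns the band value (piecewise-constant, the life-table view,
#' also used by the Monte-Carlo oracle and burden projection);
#' `"midpoint_linear"` (the default elsewhere) anchors each band's rate at
#' the band midpoint, interpolates linearly between midpoints and
#' extrapolates flat outside the outermost midpoints, giving the smooth age
#' trend implied by probabilities quoted at exact ages. Ages outside the
#' table range take the nearest band's value in either scheme.
#'
#' @param table a [rate_table()].
#' @param sex `"F"` or `"M"`.
#' @param age numeric vector of exact ages in years.
#' @param scheme `"midpoint_linear"` or `"step"`.
#' @return numeric vector of hazards per person-year (rate / 100,000).
#' @examples
#' tab <- rate_table(data.frame(
#'   sex = rep(c("F", "M"), each = 2),
#'   age_low = c(60, 65, 60, 65), age_high = c(65, 70, 65, 70),
#'   rate = c(200, 400, 150, 300)), outcome = "hip_fracture")
#' hazard_at(tab, "F", 62, scheme = "step")            # 200/1e5
#' hazard_at(tab, "F", 65, scheme = "midpoint_linear") # midpoint average
#' @export
hazard_at <- function(table, sex, age,
                      scheme = c("midpoint_linear", "step")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "rate_table"))
  if (length(sex) != 1 || !sex %in% SEXES) stop("unknown sex: ", sex)
  b <- table[table$sex == sex, , drop = FALSE]
  if (scheme == "step") {
    i <- findInterval(age, b$age_low)
    i[i < 1] <- 1L
    return(b$rate[i] / 1e5)
  }
  if (nrow(b) == 1) {
    return(rep(b$rate / 1e5, length(age)))
  }
  mids <- band_midpoints(b)
  stats::approx(mids, b$rate, xout = age, rule = 2)$y / 1e5
}

#' Construct a MOF:hip incidence ratio table
#'
#' Holds, per sex and age band, the ratio of major-osteoporotic-fracture
#' incidence to hip-fracture incidence. Surrogate models borrow these ratios
#' from registers with complete fracture ascertainment (classically Malmo,
#' Sweden) on the assumption that the age/sex pattern of MOF relative to hip
#' fracture travels across countries even where absolute rates do not.
#'
#' @param data data.frame with columns `sex`, `age_low`, `age_high`, `ratio`
#'   (positive).
#' @return a `ratio_table` data.frame, sorted by sex then age.
#' @export
ratio_table <- function(data) {
  req <- c("sex", "age_low", "age_high", "ratio")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("ratio table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(
    sex = as.character(data$sex),
    age_low = as.numeric(data$age_low),
    age_high = suppressWarnings(as.numeric(data$age_high)),
    ratio = as.numeric(data$ratio),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$ratio) | df$ratio <= 0)
  if (length(bad)) {
    stop("non-positive or missing ratio in row(s) ",
         paste(bad, collapse = ", "))
  }
  df <- df[order(df$sex, df$age_low), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ratio_table", "data.frame"))
}

#' @rdname ratio_table
#' @param path CSV file with the `ratio_table` columns.
#' @export
read_ratio_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ratio_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

band_key <- function(df) {
  paste(df$sex, df$age_low, ifelse(is.na(df$age_high), "open", df$age_high))
}

#' Impute MOF incidence from hip incidence
#'
#' Multiplies each (sex, age band) hip-fracture rate by the matching MOF:hip
#' ratio, yielding an incidence table for major osteoporotic fracture where
#' only hip-fracture incidence was observed. Band structure and sex set are
#' preserved exactly.
#'
#' @param hip a [rate_table()] with outcome `"hip_fracture"`.
#' @param ratios a [ratio_table()] on the same band structure.
#' @return a [rate_table()] with outcome `"mof"`.
#' @export
impute_mof_incidence <- function(hip, ratios) {
  stopifnot(inherits(hip, "rate_table"), inherits(ratios, "ratio_table"))
  if (attr(hip, "outcome") != "hip_fracture") {
    stop("impute_mof_incidence expects a hip_fracture incidence table, got ",
         attr(hip, "outcome"))
  }
  m <- match(band_key(hip), band_key(ratios))
  if (anyNA(m) || nrow(hip) != nrow(ratios)) {
    stop("band structure of the ratio table does not match the hip table")
  }
  out <- as.data.frame(hip)
  out$rate <- out$rate * ratios$ratio[m]
  rate_table(out, outcome = "mof",
             source_label = paste0(attr(hip, "source_label"),
                                   " x MOF:hip ratios"))
}
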
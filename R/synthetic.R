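# Seeded synthetic-data generators.
#
# No individual-level data are redistributable, so every pipeline stage is
# exercised on generated inputs carrying the statistical structure the
# analysis assumes: a referral cohort with specified age/BMI moments and
# risk-factor prevalences, Gompertz-like (log-linear in age) incidence and
# mortality tables, and an ageing population pyramid. All generators are
# deterministic under their seed and their outputs pass the package's
# validators.

#' Specification for one sex of a synthetic referral cohort
#'
#' Ages are truncated normal on `age_range` (referral cohorts recruit from
#' 40; the model range tops out at 90), BMI truncated normal above
#' `bmi_min`, and the seven clinical risk factors independent Bernoulli
#' draws at the given prevalences. Women receive a postmenopausal flag drawn
#' from a logistic curve in age crossing 0.5 at `menopause_age`.
#'
#' @param n number of people.
#' @param age_mean,age_sd parent-normal age parameters (years).
#' @param bmi_mean,bmi_sd parent-normal BMI parameters (kg/m2).
#' @param prevalences named vector of factor prevalences in `[0, 1]`
#'   (names among the seven risk factors; absent factors default to 0).
#' @param age_range truncation bounds for age (default `c(40, 90)`).
#' @param bmi_min lower truncation for BMI (default 14).
#' @param menopause_age age at which the postmenopausal probability crosses
#'   0.5 (women only).
#' @param menopause_scale logistic scale in years (smaller = sharper).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n, age_mean, age_sd, bmi_mean, bmi_sd,
                        prevalences = NULL, age_range = c(40, 90),
                        bmi_min = 14, menopause_age = 50,
                        menopause_scale = 2.5) {
  stopifnot(n >= 1, age_sd > 0, bmi_sd > 0, length(age_range) == 2,
            age_range[1] < age_range[2])
  prev <- stats::setNames(rep(0, length(RISK_FACTORS)), RISK_FACTORS)
  if (!is.null(prevalences)) {
    unknown <- setdiff(names(prevalences), RISK_FACTORS)
    if (length(unknown)) {
      stop("unknown risk factor(s): ", paste(unknown, collapse = ", "))
    }
    prev[names(prevalences)] <- as.numeric(prevalences)
  }
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]")
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, prevalences = prev,
                 age_range = age_range, bmi_min = bmi_min,
                 menopause_age = menopause_age,
                 menopause_scale = menopause_scale),
            class = "cohort_spec")
}

#' Default referral-cohort specification
#'
#' Marginals typical of an osteoporosis referral population: men around age
#' 52 (SD 10) with high smoking/alcohol prevalence, women around 54 (SD 10)
#' with roughly a third carrying a prior fracture.
#'
#' @return named list with elements `M` and `F`, each a [cohort_spec()].
#' @export
default_cohort_spec <- function() {
  list(
    M = cohort_spec(403, age_mean = 51.6, age_sd = 10.4,
                    bmi_mean = 26.8, bmi_sd = 4.6,
                    prevalences = c(prior_fracture = 0.39,
                                    parent_hip_fracture = 0.26,
                                    current_smoking = 0.42,
                                    glucocorticoids = 0.05,
                                    rheumatoid_arthritis = 0.08,
                                    secondary_osteoporosis = 0.26,
                                    alcohol_3plus = 0.39)),
    F = cohort_spec(454, age_mean = 53.9, age_sd = 10.0,
                    bmi_mean = 27.3, bmi_sd = 4.9,
                    prevalences = c(prior_fracture = 0.31,
                                    parent_hip_fracture = 0.25,
                                    current_smoking = 0.08,
                                    glucocorticoids = 0.06,
                                    rheumatoid_arthritis = 0.10,
                                    secondary_osteoporosis = 0.24,
                                    alcohol_3plus = 0.08))
  )
}

#' Generate a synthetic referral cohort
#'
#' @param spec a named list of [cohort_spec()]s keyed by sex (`"M"`, `"F"`),
#'   or a single `cohort_spec` together with `sex`.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param sex sex label when `spec` is a single `cohort_spec`.
#' @return data.frame with columns `id`, `sex`, `age`, `bmi`,
#'   `postmenopausal` (NA for men) and the seven logical risk factors.
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed, sex = NULL) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (inherits(spec, "cohort_spec")) {
    if (is.null(sex)) stop("supply sex for a single cohort_spec")
    spec <- stats::setNames(list(spec), sex)
  }
  stopifnot(all(names(spec) %in% SEXES))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  parts <- lapply(names(spec), function(s) {
    sp <- spec[[s]]
    age <- rtnorm(sp$n, sp$age_mean, sp$age_sd,
                  lower = sp$age_range[1], upper = sp$age_range[2])
    bmi <- rtnorm(sp$n, sp$bmi_mean, sp$bmi_sd, lower = sp$bmi_min)
    d <- data.frame(sex = s, age = age, bmi = bmi,
                    stringsAsFactors = FALSE)
    d$postmenopausal <- if (s == "F") {
      stats::runif(sp$n) <
        stats::plogis((age - sp$menopause_age) / sp$menopause_scale)
    } else {
      NA
    }
    for (f in RISK_FACTORS) {
      d[[f]] <- stats::rbinom(sp$n, 1, sp$prevalences[[f]]) == 1L
    }
    d
  })
  out <- do.call(rbind, parts)
  out <- cbind(id = sprintf("P%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gompertz-like rate table
#'
#' Band rates follow `baseline * exp(slope * (band midpoint - anchor_age))`
#' per 100,000 person-years — the exponential rise with age characteristic
#' of both hip-fracture incidence and adult all-cause mortality.
#'
#' @param outcome `"hip_fracture"`, `"mof"` or `"death"`.
#' @param baseline named vector `c(F = , M = )`: rate per 100,000
#'   person-years at `anchor_age`.
#' @param slope named vector `c(F = , M = )`: log-rate increase per year of
#'   age.
#' @param anchor_age age the baseline refers to (default 50).
#' @param age_low lower edges of the 5-year bands (default 40-90); the top
#'   band is open-ended.
#' @return a [rate_table()].
#' @export
gompertz_rate_table <- function(outcome, baseline, slope, anchor_age = 50,
                                age_low = seq(40, 90, by = 5)) {
  stopifnot(all(SEXES %in% names(baseline)), all(SEXES %in% names(slope)),
            all(baseline > 0))
  n <- length(age_low)
  age_high <- c(age_low[-1], NA)
  w <- if (n > 1) age_low[n] - age_low[n - 1] else 5
  mids <- ifelse(is.na(age_high), age_low + w / 2, (age_low + age_high) / 2)
  rows <- lapply(SEXES, function(s) {
    data.frame(sex = s, age_low = age_low, age_high = age_high,
               rate = baseline[[s]] * exp(slope[[s]] * (mids - anchor_age)),
               stringsAsFactors = FALSE)
  })
  rate_table(do.call(rbind, rows), outcome = outcome,
             source_label = "synthetic Gompertz")
}

#' Generate a consistent set of synthetic hazard tables
#'
#' Hip-fracture incidence and all-cause mortality with realistic orders of
#' magnitude: hip incidence near 25-30 per 100,000 at age 50 rising about
#' tenfold by 75; mortality a few hundred per 100,000 at 50 (higher in men)
#' rising Gompertz-like to roughly 10% a year by 90.
#'
#' @param hip_baseline,hip_slope,death_baseline,death_slope named `c(F=, M=)`
#'   parameters passed to [gompertz_rate_table()].
#' @param age_low band grid (default 40-90 by 5, open top band).
#' @return list with elements `hip` and `death`, each a [rate_table()].
#' @export
generate_rate_tables <- function(hip_baseline = c(F = 30, M = 25),
                                 hip_slope = c(F = 0.10, M = 0.085),
                                 death_baseline = c(F = 250, M = 550),
                                 death_slope = c(F = 0.095, M = 0.09),
                                 age_low = seq(40, 90, by = 5)) {
  list(hip = gompertz_rate_table("hip_fracture", hip_baseline, hip_slope,
                                 age_low = age_low),
       death = gompertz_rate_table("death", death_baseline, death_slope,
                                   age_low = age_low))
}

#' Default synthetic MOF:hip ratio table
#'
#' Ratios declining with age (many forearm/humerus fractures relative to hip
#' in the young-old, converging towards hip dominance in the oldest), in the
#' pattern reported by registers with full fracture ascertainment.
#'
#' @return a [ratio_table()] on the 40-90+ band grid.
#' @export
default_ratio_table <- function() {
  age_low <- seq(40, 90, by = 5)
  age_high <- c(age_low[-1], NA)
  ratio_table(data.frame(
    sex = rep(c("F", "M"), each = length(age_low)),
    age_low = rep(age_low, 2),
    age_high = rep(age_high, 2),
    ratio = c(8.0, 7.8, 7.2, 6.5, 5.6, 4.7, 3.8, 3.0, 2.4, 2.0, 1.8,
              6.0, 5.8, 5.3, 4.8, 4.2, 3.6, 3.0, 2.5, 2.1, 1.8, 1.6)))
}

#' Generate an ageing series of population pyramids
#'
#' Multiplies each band's head count by its annual growth factor, compounded
#' from the first year: `count[y] = count[base] * growth^(y - years[1])`.
#' Growth above 1 in the old bands and at or below 1 in the young bands
#' emulates a medium-variant ageing projection.
#'
#' @param base_pyramid data.frame with `sex`, `age_low`, `age_high`,
#'   `count` — the pyramid of the first year.
#' @param growth positive annual growth factor(s), recycled over the rows of
#'   `base_pyramid`.
#' @param years calendar years; the first is the base.
#' @return a multi-year [population_pyramids()] data.frame.
#' @export
generate_population_series <- function(base_pyramid, growth, years) {
  stopifnot(all(growth > 0), length(years) >= 1)
  growth <- rep_len(growth, nrow(base_pyramid))
  out <- do.call(rbind, lapply(years, function(y) {
    d <- base_pyramid[, c("sex", "age_low", "age_high", "count")]
    d$count <- d$count * growth^(y - years[1])
    cbind(year = y, d)
  }))
  population_pyramids(out)
}
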
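# Intervention and assessment thresholds.
#
# The intervention threshold (IT) at each age is the 10-year MOF probability
# of a woman of that age with a prior fragility fracture, no other clinical
# risk factors and the reference BMI — the "risk-equivalence" rule: anyone
# whose probability matches that of a woman who already fractured merits
# treatment. The lower assessment threshold (LAT) is the same calculation
# without the prior fracture; the upper assessment threshold (UAT) is 1.2
# times the IT. Hip thresholds are the hip-probability outputs of the same
# two defining profiles.

threshold_profiles <- function(model, ages, prior_fracture) {
  nd <- data.frame(age = ages, sex = "F",
                   bmi = model$rr_model$bmi_reference,
                   prior_fracture = prior_fracture)
  predict(model, nd, percent = TRUE)
}

#' Lower assessment threshold by age
#'
#' Ten-year probabilities (%) for a woman with no clinical risk factors at
#' the reference BMI: below this probability neither treatment nor a BMD
#' measurement is indicated.
#'
#' @param model a [frax_surrogate()] model.
#' @param ages ages in years (model range 40-90).
#' @return data.frame with columns `age`, `mof`, `hip` (probability %).
#' @export
lower_assessment_threshold <- function(model, ages = seq(40, 90, by = 5)) {
  p <- threshold_profiles(model, ages, prior_fracture = FALSE)
  data.frame(age = ages, mof = p$p_mof_10y, hip = p$p_hip_10y)
}

#' Intervention threshold by age
#'
#' Ten-year probabilities (%) for a woman with a prior fragility fracture,
#' no other risk factors, at the reference BMI — the treatment threshold.
#'
#' @inheritParams lower_assessment_threshold
#' @return data.frame with columns `age`, `mof`, `hip` (probability %).
#' @export
intervention_threshold <- function(model, ages = seq(40, 90, by = 5)) {
  p <- threshold_profiles(model, ages, prior_fracture = TRUE)
  data.frame(age = ages, mof = p$p_mof_10y, hip = p$p_hip_10y)
}

#' Upper assessment threshold from the intervention threshold
#'
#' `1.2 * it`, the probability above which treatment can be recommended
#' without a BMD measurement. Full precision is returned; printed tables
#' round half-up to two decimals.
#'
#' @param it intervention threshold probability (%) — scalar or vector.
#' @return `1.2 * it`.
#' @export
upper_assessment_threshold <- function(it) {
  if (any(is.na(it)) || any(it < 0)) {
    stop("intervention threshold must be non-negative")
  }
  1.2 * it
}

#' Build an age-by-threshold table
#'
#' One row per age combining LAT, IT and UAT for MOF and hip probabilities,
#' all in percent at full precision; the print method rounds half-up to two
#' decimals as such tables are conventionally published.
#'
#' @inheritParams lower_assessment_threshold
#' @param ages sorted ascending ages.
#' @return a `threshold_table` data.frame with columns `age`, `lat_mof`,
#'   `it_mof`, `uat_mof`, `lat_hip`, `it_hip`, `uat_hip`.
#' @export
threshold_table <- function(model, ages = seq(40, 90, by = 5)) {
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be sorted strictly ascending")
  }
  lat <- lower_assessment_threshold(model, ages)
  it <- intervention_threshold(model, ages)
  structure(data.frame(age = ages,
                       lat_mof = lat$mof, it_mof = it$mof,
                       uat_mof = upper_assessment_threshold(it$mof),
                       lat_hip = lat$hip, it_hip = it$hip,
                       uat_hip = upper_assessment_threshold(it$hip)),
            class = c("threshold_table", "data.frame"))
}

#' @export
print.threshold_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- setdiff(names(y), "age")
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Compare probability curves under two mortality schedules
#'
#' Same incidence, two all-cause mortality tables: isolates the effect of
#' competing mortality on the age-specific probability curve (higher
#' mortality lowers fracture probability at every age). This is how a
#' surrogate model is compared with its donor-country model.
#'
#' @param incidence a [rate_table()] (`"hip_fracture"` or `"mof"`).
#' @param mortality_a,mortality_b [rate_table()]s with outcome `"death"`.
#' @param ages age grid (years, within 40-90).
#' @param sex,bmi profile of the reference individual (default: woman at
#'   BMI 27 with no risk factors).
#' @param rr_model an [relative_risk_model()].
#' @param scheme hazard scheme for [hazard_at()].
#' @return data.frame with columns `age`, `p_a`, `p_b` (probability %),
#'   with the incidence outcome as attribute `outcome`.
#' @export
compare_mortality_scenarios <- function(incidence, mortality_a, mortality_b,
                                        ages = seq(40, 90, by = 5),
                                        sex = "F", bmi = 27,
                                        rr_model = rr_neutral(),
                                        scheme = c("midpoint_linear",
                                                   "step")) {
  scheme <- match.arg(scheme)
  one <- function(mort, a) {
    pr <- risk_profile(age = a, sex = sex, bmi = bmi)
    res <- ten_year_probability(pr, incidence, mort, rr_model,
                                scheme = scheme)
    oc <- attr(incidence, "outcome")
    100 * if (oc == "hip_fracture") res$p_hip_10y else res$p_mof_10y
  }
  structure(data.frame(age = ages,
                       p_a = vapply(ages, function(a) one(mortality_a, a), 0),
                       p_b = vapply(ages, function(a) one(mortality_b, a), 0)),
            outcome = attr(incidence, "outcome"))
}
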
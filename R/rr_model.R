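# Clinical-risk-factor layer.
#
# The proprietary FRAX coefficient set is not public; the package instead
# exposes a configurable relative-risk layer: one multiplicative relative
# risk per binary clinical risk factor and outcome, a BMI gradient anchored
# at a reference BMI, and population prevalences used to calibrate the layer
# so that a population with those prevalences reproduces the published
# incidence on average. The shipped configuration holds literature-style
# placeholder values and must not be mistaken for the FRAX coefficients.

RISK_FACTORS <- c("prior_fracture", "parent_hip_fracture", "current_smoking",
                  "glucocorticoids", "rheumatoid_arthritis",
                  "secondary_osteoporosis", "alcohol_3plus")

RR_OUTCOMES <- c("mof", "hip")

#' Clinical-risk-factor relative-risk model
#'
#' Defines how a person's clinical risk factors and BMI scale the population
#' incidence hazard. For each outcome (MOF, hip) every binary factor carries
#' a multiplicative relative risk, and BMI contributes
#' `bmi_rr_per_5^((bmi_reference - bmi)/5)` — risk rising for each 5 kg/m2
#' below the reference. Population prevalences calibrate the layer (see
#' [adjust_hazard()]): the incidence tables describe the whole population,
#' so an individual's hazard is the population hazard times
#' RR(individual)/RR(population average).
#'
#' @param mof,hip named numeric vectors of relative risks (> 0) for (a subset
#'   of) the seven factors `r paste(RISK_FACTORS, collapse = ", ")`;
#'   unnamed factors default to 1.
#' @param bmi_reference reference BMI in kg/m2 (default 27).
#' @param bmi_rr_per_5 named vector `c(mof = , hip = )`: relative risk per
#'   5 kg/m2 of BMI below the reference (1 = no BMI effect).
#' @param prevalences named vector of population prevalences in `[0, 1]`;
#'   unnamed factors default to 0 (no calibration correction).
#' @return an object of class `rr_model`.
#' @seealso [rr_neutral()], [read_rr_model()], [adjust_hazard()]
#' @export
relative_risk_model <- function(mof = NULL, hip = NULL, bmi_reference = 27,
                                bmi_rr_per_5 = c(mof = 1, hip = 1),
                                prevalences = NULL) {
  fill <- function(x, default, what) {
    out <- stats::setNames(rep(default, length(RISK_FACTORS)), RISK_FACTORS)
    if (!is.null(x)) {
      unknown <- setdiff(names(x), RISK_FACTORS)
      if (length(unknown)) {
        stop("unknown risk factor(s) in ", what, ": ",
             paste(unknown, collapse = ", "))
      }
      out[names(x)] <- as.numeric(x)
    }
    out
  }
  rr <- list(mof = fill(mof, 1, "mof"), hip = fill(hip, 1, "hip"))
  for (o in RR_OUTCOMES) {
    if (any(!is.finite(rr[[o]]) | rr[[o]] <= 0)) {
      stop("all relative risks must be positive (outcome ", o, ")")
    }
  }
  prev <- fill(prevalences, 0, "prevalences")
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]")
  if (!all(RR_OUTCOMES %in% names(bmi_rr_per_5))) {
    stop("bmi_rr_per_5 needs named entries for mof and hip")
  }
  bmi_rr <- c(mof = unname(bmi_rr_per_5[["mof"]]),
              hip = unname(bmi_rr_per_5[["hip"]]))
  if (any(bmi_rr <= 0)) stop("bmi_rr_per_5 must be positive")
  if (!is.numeric(bmi_reference) || bmi_reference <= 0) {
    stop("bmi_reference must be a positive BMI")
  }
  structure(list(rr = rr, bmi_reference = bmi_reference,
                 bmi_rr_per_5 = bmi_rr, prevalences = prev),
            class = "rr_model")
}

#' Neutral relative-risk model
#'
#' All relative risks 1, no BMI gradient, all prevalences 0: every profile
#' receives the unmodified population hazard. The default for model
#' construction, and the configuration under which the intervention
#' threshold collapses onto the no-risk-factor curve.
#'
#' @return an `rr_model` with no risk-factor effects.
#' @export
rr_neutral <- function() relative_risk_model()

#' Read a relative-risk configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' bmi_reference: 27
#' bmi_rr_per_5: {mof: 1.2, hip: 1.4}
#' relative_risks:
#'   mof: {prior_fracture: 1.8, ...}
#'   hip: {prior_fracture: 1.8, ...}
#' population_prevalences: {prior_fracture: 0.25, ...}
#' ```
#' A placeholder configuration ships at
#' `system.file("extdata", "rr_placeholder.yaml", package = "surfrax")`.
#'
#' @param path YAML file path.
#' @return an [relative_risk_model()] object.
#' @export
read_rr_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  relative_risk_model(
    mof = unlist(cfg$relative_risks$mof),
    hip = unlist(cfg$relative_risks$hip),
    bmi_reference = if (is.null(cfg$bmi_reference)) 27 else cfg$bmi_reference,
    bmi_rr_per_5 = c(mof = if (is.null(cfg$bmi_rr_per_5$mof)) 1 else cfg$bmi_rr_per_5$mof,
                     hip = if (is.null(cfg$bmi_rr_per_5$hip)) 1 else cfg$bmi_rr_per_5$hip),
    prevalences = unlist(cfg$population_prevalences)
  )
}

#' @export
print.rr_model <- function(x, ...) {
  cat("Clinical-risk-factor relative-risk model\n")
  cat("  BMI reference:", x$bmi_reference, "kg/m2; RR per 5 kg/m2 below:",
      "MOF", x$bmi_rr_per_5[["mof"]], "| hip", x$bmi_rr_per_5[["hip"]], "\n")
  tab <- data.frame(mof = x$rr$mof, hip = x$rr$hip,
                    prevalence = x$prevalences)
  print(tab, ...)
  invisible(x)
}

#' One person's risk profile
#'
#' @param age age in years, within the model range 40-90.
#' @param sex `"F"` or `"M"`.
#' @param bmi body-mass index in kg/m2 (> 0).
#' @param prior_fracture,parent_hip_fracture,current_smoking,glucocorticoids,rheumatoid_arthritis,secondary_osteoporosis,alcohol_3plus
#'   logical clinical risk factors.
#' @return an object of class `risk_profile`.
#' @export
risk_profile <- function(age, sex, bmi = 27,
                         prior_fracture = FALSE, parent_hip_fracture = FALSE,
                         current_smoking = FALSE, glucocorticoids = FALSE,
                         rheumatoid_arthritis = FALSE,
                         secondary_osteoporosis = FALSE,
                         alcohol_3plus = FALSE) {
  if (!is.numeric(age) || length(age) != 1 || age < 40 || age > 90) {
    stop("age must be a single value in the model range [40, 90]")
  }
  if (length(sex) != 1 || !sex %in% SEXES) stop("sex must be \"F\" or \"M\"")
  if (!is.numeric(bmi) || bmi <= 0) stop("bmi must be positive")
  p <- list(age = age, sex = sex, bmi = bmi,
            prior_fracture = isTRUE(prior_fracture),
            parent_hip_fracture = isTRUE(parent_hip_fracture),
            current_smoking = isTRUE(current_smoking),
            glucocorticoids = isTRUE(glucocorticoids),
            rheumatoid_arthritis = isTRUE(rheumatoid_arthritis),
            secondary_osteoporosis = isTRUE(secondary_osteoporosis),
            alcohol_3plus = isTRUE(alcohol_3plus))
  structure(p, class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  on <- RISK_FACTORS[vapply(RISK_FACTORS, function(f) x[[f]], logical(1))]
  cat("Risk profile: ", x$sex, ", age ", x$age, ", BMI ", x$bmi, "; factors: ",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

# Individual relative risk: product over factors present, times BMI term.
relative_risk <- function(profile, rr_model, outcome = c("mof", "hip")) {
  outcome <- match.arg(outcome)
  rr <- rr_model$rr[[outcome]]
  on <- vapply(RISK_FACTORS, function(f) isTRUE(profile[[f]]), logical(1))
  bmi_term <- rr_model$bmi_rr_per_5[[outcome]] ^
    ((rr_model$bmi_reference - profile$bmi) / 5)
  prod(rr[on]) * bmi_term
}

# Population-average relative risk implied by the configured prevalences.
population_relative_risk <- function(rr_model, outcome = c("mof", "hip")) {
  outcome <- match.arg(outcome)
  rr <- rr_model$rr[[outcome]]
  prev <- rr_model$prevalences
  prod(prev * rr + (1 - prev))
}

#' Scale a population hazard to an individual
#'
#' Returns `h_base * RR(profile) / RR(population)`, where `RR(profile)` is
#' the product of the per-factor relative risks over the factors the profile
#' carries times the BMI term, and `RR(population)` is the prevalence-weighted
#' average relative risk `prod(prev * RR + (1 - prev))`. The division
#' calibrates the layer: averaging the adjusted hazard over a population with
#' the configured prevalences recovers `h_base`, so the incidence tables keep
#' their population meaning.
#'
#' @param h_base population hazard(s) per person-year.
#' @param profile a [risk_profile()].
#' @param rr_model an [relative_risk_model()].
#' @param outcome `"mof"` or `"hip"`.
#' @return adjusted hazard(s), same length as `h_base`.
#' @export
adjust_hazard <- function(h_base, profile, rr_model,
                          outcome = c("mof", "hip")) {
  outcome <- match.arg(outcome)
  if (any(h_base < 0)) stop("hazards must be non-negative")
  h_base * relative_risk(profile, rr_model, outcome) /
    population_relative_risk(rr_model, outcome)
}
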
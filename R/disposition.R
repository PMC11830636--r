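# Cohort disposition against the thresholds.
#
# A referral cohort is first restricted to the population in whom treatment
# eligibility is assessed (men 50+, postmenopausal women), then each person
# is placed in exactly one category: prior fracture (eligible outright), or
# by 10-year MOF probability relative to the age-specific LAT/IT/UAT.
# p = IT counts as eligible ("equalled or exceeded the intervention
# threshold"); the boundary affects measure-zero cases only.

DISPOSITION_LEVELS <- c("eligible_prior_fracture", "low_risk",
                        "bmd_test_recommended", "eligible_between_it_uat",
                        "eligible_high_risk")

#' Restrict a cohort to the eligibility-assessment population
#'
#' Keeps men aged 50 or more and women flagged postmenopausal. Women without
#' a recorded menopause status cannot be assessed and are dropped with a
#' warning.
#'
#' @param cohort data.frame with at least `sex` and `age`; for women a
#'   `postmenopausal` column (logical or 0/1).
#' @return the filtered cohort.
#' @export
filter_impact_sample <- function(cohort) {
  stopifnot(all(c("sex", "age") %in% names(cohort)))
  sex <- as.character(cohort$sex)
  pm <- if ("postmenopausal" %in% names(cohort)) {
    as.logical(cohort$postmenopausal)
  } else {
    rep(NA, nrow(cohort))
  }
  women <- sex == "F"
  unknown <- women & is.na(pm)
  if (any(unknown)) {
    warning(sum(unknown),
            " women without a recorded menopause status were dropped")
  }
  keep <- (sex == "M" & cohort$age >= 50) | (women & !is.na(pm) & pm)
  cohort[keep, , drop = FALSE]
}

#' Classify a person against the age-specific thresholds
#'
#' Anyone with a prior fracture is eligible outright. Otherwise the 10-year
#' MOF probability `p` (in %) is compared with the thresholds at the
#' person's age: `p <= LAT` low risk; `LAT < p < IT` BMD test recommended;
#' `IT <= p <= UAT` eligible (and BMD still informative); `p > UAT` eligible
#' at high risk, no BMD needed.
#'
#' @param p_mof 10-year MOF probability in percent.
#' @param prior_fracture logical.
#' @param lat,it,uat thresholds in percent at the person's age.
#' @return factor with levels
#'   `r paste(DISPOSITION_LEVELS, collapse = ", ")`; vectorised with
#'   recycling.
#' @export
classify_person <- function(p_mof, prior_fracture, lat, it, uat) {
  n <- max(length(p_mof), length(prior_fracture), length(lat))
  p_mof <- rep_len(p_mof, n)
  prior_fracture <- rep_len(as.logical(prior_fracture), n)
  lat <- rep_len(lat, n)
  it <- rep_len(it, n)
  uat <- rep_len(uat, n)
  if (any(is.na(p_mof) & !prior_fracture)) {
    stop("MOF probability required for records without a prior fracture")
  }
  if (any(lat > it | it > uat)) stop("thresholds must satisfy lat <= it <= uat")
  out <- ifelse(prior_fracture, "eligible_prior_fracture",
         ifelse(p_mof <= lat, "low_risk",
         ifelse(p_mof < it, "bmd_test_recommended",
         ifelse(p_mof <= uat, "eligible_between_it_uat",
                "eligible_high_risk"))))
  factor(out, levels = DISPOSITION_LEVELS)
}

# Interpolate the threshold columns at arbitrary ages; ages outside the
# table's range are an error (the thresholds are undefined there).
thresholds_at_age <- function(thresholds, ages) {
  stopifnot(is.data.frame(thresholds), "age" %in% names(thresholds))
  if (any(ages < min(thresholds$age) | ages > max(thresholds$age))) {
    stop("age outside the threshold table range [",
         min(thresholds$age), ", ", max(thresholds$age), "]")
  }
  out <- data.frame(age = ages)
  for (cl in setdiff(names(thresholds), "age")) {
    out[[cl]] <- stats::approx(thresholds$age, thresholds[[cl]],
                               xout = ages)$y
  }
  out
}

#' Classify every record in a cohort
#'
#' Adds a `category` column. Records carrying a precomputed `p_mof_10y`
#' column (percent) are classified directly; otherwise a model must be
#' supplied and probabilities are computed with [predict.frax_surrogate()].
#'
#' @param cohort data.frame with `sex`, `age`, `prior_fracture`, risk-factor
#'   and `bmi` columns, optionally `p_mof_10y` (%).
#' @param thresholds a [threshold_table()] (or data.frame with `age`,
#'   `lat_mof`, `it_mof`, `uat_mof`).
#' @param model optional [frax_surrogate()] used when `p_mof_10y` is absent.
#' @return `cohort` with columns `p_mof_10y` and `category`.
#' @export
classify_cohort <- function(cohort, thresholds, model = NULL) {
  if (!"p_mof_10y" %in% names(cohort) || anyNA(cohort$p_mof_10y)) {
    if (is.null(model)) {
      stop("cohort lacks p_mof_10y; supply a frax_surrogate model")
    }
    cohort$p_mof_10y <- predict(model, cohort, percent = TRUE)$p_mof_10y
  }
  thr <- thresholds_at_age(thresholds, cohort$age)
  cohort$category <- classify_person(cohort$p_mof_10y,
                                     cohort$prior_fracture,
                                     thr$lat_mof, thr$it_mof, thr$uat_mof)
  cohort
}

#' Summarise treatment-eligibility disposition by sex
#'
#' Classifies the cohort and tabulates, per sex: every disposition category
#' plus the derived aggregates `eligible_total` (prior fracture + high risk +
#' between IT and UAT) and `bmd_tests` (everyone with LAT < p <= UAT, i.e.
#' BMD-test-recommended + between IT and UAT). Percentages are of the sex
#' total; means of the MOF probability and BMI describe each category.
#'
#' @inheritParams classify_cohort
#' @return a `disposition_summary` data.frame with columns `sex`, `group`,
#'   `n`, `pct`, `mean_p_mof`, `mean_bmi` (full precision; the print method
#'   rounds percentages half-up to one decimal).
#' @export
summarize_disposition <- function(cohort, thresholds, model = NULL) {
  groups <- c("all", "prior_fracture", "low_risk", "bmd_test_recommended",
              "between_it_uat", "high_risk", "eligible_total", "bmd_tests")
  if (nrow(cohort) == 0) {
    out <- expand.grid(group = groups, sex = c("F", "M"),
                       stringsAsFactors = FALSE)[, 2:1]
    out$n <- 0L
    out$pct <- 0
    out$mean_p_mof <- NA_real_
    out$mean_bmi <- NA_real_
    return(structure(out, class = c("disposition_summary", "data.frame")))
  }
  cl <- classify_cohort(cohort, thresholds, model)
  rows <- list()
  for (s in intersect(c("F", "M"), unique(as.character(cl$sex)))) {
    d <- cl[cl$sex == s, , drop = FALSE]
    total <- nrow(d)
    members <- list(
      all = rep(TRUE, total),
      prior_fracture = d$category == "eligible_prior_fracture",
      low_risk = d$category == "low_risk",
      bmd_test_recommended = d$category == "bmd_test_recommended",
      between_it_uat = d$category == "eligible_between_it_uat",
      high_risk = d$category == "eligible_high_risk",
      eligible_total = d$category %in% c("eligible_prior_fracture",
                                         "eligible_between_it_uat",
                                         "eligible_high_risk"),
      bmd_tests = d$category %in% c("bmd_test_recommended",
                                    "eligible_between_it_uat")
    )
    for (g in groups) {
      m <- members[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, group = g, n = sum(m),
        pct = if (total > 0) 100 * sum(m) / total else 0,
        mean_p_mof = if (sum(m)) mean(d$p_mof_10y[m]) else NA_real_,
        mean_bmi = if (sum(m) && "bmi" %in% names(d)) {
          mean(d$bmi[m])
        } else {
          NA_real_
        },
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("disposition_summary", "data.frame"))
}

#' @export
print.disposition_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct <- round_half_up(y$pct, 1)
  y$mean_p_mof <- round_half_up(y$mean_p_mof, 1)
  y$mean_bmi <- round_half_up(y$mean_bmi, 1)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Baseline characteristics table
#'
#' Per-sex descriptive statistics in the style of a baseline-characteristics
#' table:
#' mean (SD) for continuous variables, n (%) for the binary risk factors
#' (percentages rounded half-up to integers in the print method). With a
#' single record the SD is reported as 0 by convention, with a warning.
#'
#' @param cohort data.frame with `sex` and any of `age`, `bmi`,
#'   `p_mof_10y`, `p_hip_10y` plus the binary risk-factor columns.
#' @return a `cohort_characteristics` data.frame with columns `sex`,
#'   `variable`, `n`, `mean`, `sd`, `count`, `pct`.
#' @export
cohort_characteristics <- function(cohort) {
  stopifnot("sex" %in% names(cohort))
  cont <- intersect(c("age", "bmi", "p_mof_10y", "p_hip_10y"), names(cohort))
  bins <- intersect(RISK_FACTORS, names(cohort))
  rows <- list()
  for (s in intersect(c("F", "M"), unique(as.character(cohort$sex)))) {
    d <- cohort[cohort$sex == s, , drop = FALSE]
    n <- nrow(d)
    if (n == 1 && length(cont)) {
      warning("single record for sex ", s,
              "; SDs reported as 0 by convention")
    }
    for (v in cont) {
      sdv <- if (n > 1) stats::sd(d[[v]]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, variable = v, n = n, mean = mean(d[[v]]), sd = sdv,
        count = NA_integer_, pct = NA_real_, stringsAsFactors = FALSE)
    }
    for (v in bins) {
      k <- sum(as.logical(d[[v]]))
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, variable = v, n = n, mean = NA_real_, sd = NA_real_,
        count = k, pct = if (n > 0) 100 * k / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("cohort_characteristics", "data.frame"))
}

#' @export
print.cohort_characteristics <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean <- round_half_up(y$mean, 1)
  y$sd <- round_half_up(y$sd, 1)
  y$pct <- round_half_up(y$pct, 0)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
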
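# The surrogate model object.
#
# A surrogate country model pairs fracture incidence borrowed from a
# neighbouring country with the index country's own all-cause mortality:
# fracture risk is assumed to travel across the border, competing mortality
# is not. frax_surrogate() bundles the three hazard tables with the
# relative-risk layer into one fitted-model-like object; everything
# downstream (thresholds, cohort classification, plots) consumes it.

#' Build a surrogate fracture-risk model
#'
#' Combines hip-fracture incidence (typically from a neighbouring country),
#' all-cause mortality for the index country, and either MOF:hip ratios (from
#' which MOF incidence is imputed via [impute_mof_incidence()]) or a ready
#' MOF incidence table, plus a clinical-risk-factor layer.
#'
#' @param hip_incidence [rate_table()] with outcome `"hip_fracture"`.
#' @param mortality [rate_table()] with outcome `"death"` (index country,
#'   all causes).
#' @param mof_ratios optional [ratio_table()] of MOF:hip incidence ratios.
#' @param mof_incidence optional [rate_table()] with outcome `"mof"`;
#'   exactly one of `mof_ratios` / `mof_incidence` must be given.
#' @param rr_model an [relative_risk_model()]; default [rr_neutral()].
#' @param scheme default hazard interpolation scheme ([hazard_at()]).
#' @param label free-text model label (defaults to the table sources).
#' @return an object of class `frax_surrogate`.
#' @examples
#' tabs <- generate_rate_tables()
#' m <- frax_surrogate(tabs$hip, tabs$death, mof_ratios = default_ratio_table())
#' predict(m, data.frame(age = 65, sex = "F"), percent = TRUE)
#' @export
frax_surrogate <- function(hip_incidence, mortality, mof_ratios = NULL,
                           mof_incidence = NULL, rr_model = rr_neutral(),
                           scheme = c("midpoint_linear", "step"),
                           label = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(hip_incidence, "rate_table"),
            inherits(mortality, "rate_table"),
            inherits(rr_model, "rr_model"))
  if (attr(hip_incidence, "outcome") != "hip_fracture") {
    stop("hip_incidence must have outcome \"hip_fracture\"")
  }
  if (attr(mortality, "outcome") != "death") {
    stop("mortality must have outcome \"death\"")
  }
  if (is.null(mof_incidence)) {
    if (is.null(mof_ratios)) {
      stop("supply mof_ratios (to impute MOF incidence) or mof_incidence")
    }
    mof_incidence <- impute_mof_incidence(hip_incidence, mof_ratios)
  } else {
    if (!is.null(mof_ratios)) {
      stop("supply only one of mof_ratios and mof_incidence")
    }
    stopifnot(inherits(mof_incidence, "rate_table"))
    if (attr(mof_incidence, "outcome") != "mof") {
      stop("mof_incidence must have outcome \"mof\"")
    }
  }
  if (is.null(label)) {
    label <- paste0("incidence: ", attr(hip_incidence, "source_label"),
                    " | mortality: ", attr(mortality, "source_label"))
  }
  structure(list(hip = hip_incidence, mof = mof_incidence,
                 mortality = mortality, rr_model = rr_model,
                 scheme = scheme, label = label),
            class = "frax_surrogate")
}

#' @export
print.frax_surrogate <- function(x, ...) {
  cat("Surrogate fracture-risk model\n")
  cat("  ", x$label, "\n", sep = "")
  cat("  age bands: ", min(x$hip$age_low), "-", max(x$hip$age_low),
      if (anyNA(x$hip$age_high)) "+" else "", ", hazard scheme: ", x$scheme,
      "\n", sep = "")
  neutral <- all(unlist(x$rr_model$rr) == 1) && all(x$rr_model$bmi_rr_per_5 == 1)
  cat("  risk-factor layer: ",
      if (neutral) "neutral (population hazards)" else "configured", "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.frax_surrogate <- function(object, ...) {
  rr <- object$rr_model
  c(stats::setNames(rr$rr$mof, paste0("mof.", names(rr$rr$mof))),
    stats::setNames(rr$rr$hip, paste0("hip.", names(rr$rr$hip))),
    mof.bmi_rr_per_5 = rr$bmi_rr_per_5[["mof"]],
    hip.bmi_rr_per_5 = rr$bmi_rr_per_5[["hip"]])
}

# Turn one data-frame row into a risk_profile; absent factor columns are
# treated as FALSE and absent BMI as the reference BMI.
profile_from_row <- function(row, rr_model) {
  args <- list(age = row$age, sex = as.character(row$sex),
               bmi = if (!is.null(row$bmi) && !is.na(row$bmi)) {
                 row$bmi
               } else {
                 rr_model$bmi_reference
               })
  for (f in RISK_FACTORS) {
    v <- row[[f]]
    args[[f]] <- !is.null(v) && !is.na(v) && as.logical(v)
  }
  do.call(risk_profile, args)
}

#' Predict ten-year probabilities for a set of profiles
#'
#' @param object a [frax_surrogate()] model.
#' @param newdata data.frame with columns `age`, `sex`, and optionally `bmi`
#'   (default: the layer's reference BMI) and the seven logical/0-1 risk
#'   factor columns (default: absent).
#' @param percent report probabilities as percentages (default `FALSE`,
#'   proportions).
#' @param ... unused.
#' @return data.frame with `p_mof_10y`, `p_hip_10y` and `survival_10y`
#'   (10-year survival under mortality alone), one row per profile.
#' @export
predict.frax_surrogate <- function(object, newdata, percent = FALSE, ...) {
  stopifnot(is.data.frame(newdata), all(c("age", "sex") %in% names(newdata)))
  n <- nrow(newdata)
  out <- data.frame(p_mof_10y = numeric(n), p_hip_10y = numeric(n),
                    survival_10y = numeric(n))
  for (i in seq_len(n)) {
    pr <- profile_from_row(newdata[i, , drop = FALSE], object$rr_model)
    res <- ten_year_probability(pr, list(object$mof, object$hip),
                                object$mortality, object$rr_model,
                                scheme = object$scheme)
    out$p_mof_10y[i] <- res$p_mof_10y
    out$p_hip_10y[i] <- res$p_hip_10y
    out$survival_10y[i] <- res$survival_10y
  }
  if (percent) {
    out$p_mof_10y <- 100 * out$p_mof_10y
    out$p_hip_10y <- 100 * out$p_hip_10y
    out$survival_10y <- 100 * out$survival_10y
  }
  out
}

#' @export
summary.frax_surrogate <- function(object, ages = seq(40, 90, by = 5), ...) {
  structure(list(model = object,
                 thresholds = threshold_table(object, ages = ages)),
            class = "summary.frax_surrogate")
}

#' @export
print.summary.frax_surrogate <- function(x, ...) {
  print(x$model)
  cat("\nAge-dependent thresholds (10-year probability, %):\n")
  print(x$thresholds)
  invisible(x)
}

#' Plot age-specific probability curves
#'
#' No-risk-factor 10-year probability against age for both sexes at the
#' reference BMI, the standard way to visualise a country model.
#'
#' @param x a [frax_surrogate()] model.
#' @param outcome `"hip"` or `"mof"`.
#' @param ages age grid (years).
#' @param ... passed to [graphics::matplot()].
#' @return the plotted data, invisibly (age, percent probability per sex).
#' @export
plot.frax_surrogate <- function(x, outcome = c("hip", "mof"),
                                ages = seq(40, 90, by = 2), ...) {
  outcome <- match.arg(outcome)
  col <- paste0("p_", if (outcome == "hip") "hip" else "mof", "_10y")
  curves <- sapply(c("F", "M"), function(s) {
    predict(x, data.frame(age = ages, sex = s), percent = TRUE)[[col]]
  })
  graphics::matplot(ages, curves, type = "l", lty = 1:2, col = c(2, 4),
                    xlab = "Age (years)",
                    ylab = paste0("10-year ", toupper(outcome),
                                  " probability (%)"), ...)
  graphics::legend("topleft", legend = c("Women", "Men"), lty = 1:2,
                   col = c(2, 4), bty = "n")
  invisible(data.frame(age = ages, F = curves[, "F"], M = curves[, "M"]))
}

#' Simulate first-event outcomes from the model
#'
#' Draws `nsim` individual 10-year trajectories for one profile under the
#' step-scheme hazards (the same simulator that backs
#' [monte_carlo_probability()]).
#'
#' @param object a [frax_surrogate()] model.
#' @param nsim number of simulated people.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param profile a [risk_profile()].
#' @param outcome `"hip"` or `"mof"`.
#' @param horizon years (default 10).
#' @param ... unused.
#' @return factor of length `nsim` with levels `event_free`, `fracture`,
#'   `death_first`.
#' @export
simulate.frax_surrogate <- function(object, nsim = 1, seed = NULL,
                                    profile, outcome = c("hip", "mof"),
                                    horizon = 10, ...) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(profile, "risk_profile"))
  tab <- if (outcome == "hip") object$hip else object$mof
  ages <- profile$age + seq_len(horizon) - 1
  h_event <- adjust_hazard(hazard_at(tab, profile$sex, ages, "step"),
                           profile, object$rr_model, outcome)
  h_death <- hazard_at(object$mortality, profile$sex, ages, "step")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  status <- simulate_first_event(h_event, h_death, nsim, horizon)
  factor(c("event_free", "fracture", "death_first")[status + 1L],
         levels = c("event_free", "fracture", "death_first"))
}
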
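# Fixtures shared across test files; everything is built in code.

# Constant-hazard table: one open-ended band per sex.
const_rate_table <- function(rate_f, rate_m = rate_f, outcome) {
  rate_table(data.frame(sex = c("F", "M"), age_low = 40, age_high = NA,
                        rate = c(rate_f, rate_m)),
             outcome = outcome)
}

# Standard synthetic Gompertz table set and a model on top of it.
synthetic_tables <- function() {
  tabs <- generate_rate_tables()
  tabs$ratios <- default_ratio_table()
  tabs$mof <- impute_mof_incidence(tabs$hip, tabs$ratios)
  tabs
}

synthetic_model <- function(rr_model = rr_neutral(),
                            scheme = "midpoint_linear") {
  tabs <- synthetic_tables()
  frax_surrogate(tabs$hip, tabs$death, mof_ratios = tabs$ratios,
                 rr_model = rr_model, scheme = scheme)
}

# Relative-risk layer with only a prior-fracture effect (used by threshold
# structure tests; magnitude is structural, not a claim about FRAX).
prior_fracture_rr <- function(rr = 1.8) {
  relative_risk_model(mof = c(prior_fracture = rr),
                      hip = c(prior_fracture = rr))
}

# A small 11-band two-sex rate table written to CSV, for I/O tests.
write_demo_csv <- function(path, rate_fun = function(mid) 10 + mid) {
  age_low <- seq(40, 90, by = 5)
  age_high <- c(seq(45, 90, by = 5), NA)
  mid <- ifelse(is.na(age_high), age_low + 2.5, (age_low + age_high) / 2)
  df <- rbind(
    data.frame(sex = "F", age_low = age_low, age_high = age_high,
               rate = rate_fun(mid)),
    data.frame(sex = "M", age_low = age_low, age_high = age_high,
               rate = rate_fun(mid) * 0.8)
  )
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}

# Expand published per-category counts into per-person records whose MOF
# probabilities sit inside the matching threshold interval at `age`.
reference_disposition_cohort <- function(counts, thresholds, age = 65) {
  t <- thresholds[thresholds$age == age, ]
  stopifnot(nrow(t) == 1)
  p_for <- c(prior_fracture = t$lat_mof / 2,
             low_risk = t$lat_mof / 2,
             bmd_test_recommended = (t$lat_mof + t$it_mof) / 2,
             between_it_uat = (t$it_mof + t$uat_mof) / 2,
             high_risk = t$uat_mof + 1)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    g <- counts$group[i]
    if (g == "all" || counts$n[i] == 0) return(NULL)
    data.frame(sex = counts$sex[i], age = age, bmi = 27,
               prior_fracture = g == "prior_fracture",
               p_mof_10y = rep(p_for[[g]], counts$n[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

extdata <- function(f) system.file("extdata", f, package = "surfrax")
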
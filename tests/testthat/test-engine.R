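# Double-decrement kernel, ten-year accumulation, risk-factor layer and the
# Monte-Carlo oracle.

test_that("interval kernel matches its closed form and limits", {
  # (2/3) * (1 - exp(-0.03)), frozen
  expect_equal(interval_event_probability(0.02, 0.01, 1),
               0.0197029776343279, tolerance = 1e-12)
  expect_identical(interval_event_probability(0, 0.05, 1), 0)
  expect_identical(interval_event_probability(0, 0, 1), 0)
  # no competing risk: 1 - exp(-h * dt)
  expect_equal(interval_event_probability(0.01, 0, 10),
               0.0951625819640405, tolerance = 1e-12)
  expect_error(interval_event_probability(-0.01, 0.1), "non-negative")
  expect_error(interval_event_probability(0.01, 0.1, dt = 0), "positive")
})

test_that("ten-year probability reproduces constant-hazard closed forms", {
  hip <- const_rate_table(100, outcome = "hip_fracture")   # h = 0.001/y
  none <- const_rate_table(0, outcome = "death")
  p <- ten_year_probability(risk_profile(65, "F"), hip, none)
  expect_equal(p$p_hip_10y, 0.00995016625083189, tolerance = 1e-9)

  # equal event and death hazards h: p = (1/2) (1 - exp(-20 h)), h = 0.01
  hip2 <- const_rate_table(1000, outcome = "hip_fracture")
  death2 <- const_rate_table(1000, outcome = "death")
  p2 <- ten_year_probability(risk_profile(65, "M"), hip2, death2)
  expect_equal(p2$p_hip_10y, 0.0906346234610091, tolerance = 1e-9)
})

test_that("event + death-first + event-free decomposes to unity within 1e-12", {
  tabs <- synthetic_tables()
  rr <- prior_fracture_rr(1.8)
  for (sex in c("F", "M")) {
    for (age in c(40, 57, 72, 90)) {
      for (prior in c(FALSE, TRUE)) {
        pr <- risk_profile(age, sex, bmi = 24, prior_fracture = prior)
        res <- ten_year_probability(pr, list(tabs$mof, tabs$hip), tabs$death,
                                    rr_model = rr)
        for (dec in res$decomposition) {
          expect_lt(abs(sum(dec) - 1), 1e-12)
          expect_true(all(dec >= 0 & dec <= 1))
        }
      }
    }
  }
})

test_that("probabilities rise with incidence and fall with mortality", {
  tabs <- synthetic_tables()
  pr <- risk_profile(62, "F")
  base <- ten_year_probability(pr, tabs$hip, tabs$death)$p_hip_10y
  for (band in c(3, 5, 8)) {  # perturb individual F bands
    inc <- as.data.frame(tabs$hip)
    inc$rate[inc$sex == "F"][band] <- inc$rate[inc$sex == "F"][band] * 1.5
    inc <- rate_table(inc, "hip_fracture")
    expect_gte(ten_year_probability(pr, inc, tabs$death)$p_hip_10y, base)

    mort <- as.data.frame(tabs$death)
    mort$rate[mort$sex == "F"][band] <- mort$rate[mort$sex == "F"][band] * 1.5
    mort <- rate_table(mort, "death")
    expect_lte(ten_year_probability(pr, tabs$hip, mort)$p_hip_10y, base)
  }
  # global perturbations move strictly
  inc <- as.data.frame(tabs$hip); inc$rate <- inc$rate * 2
  expect_gt(ten_year_probability(pr, rate_table(inc, "hip_fracture"),
                                 tabs$death)$p_hip_10y, base)
  mort <- as.data.frame(tabs$death); mort$rate <- mort$rate * 2
  expect_lt(ten_year_probability(pr, tabs$hip,
                                 rate_table(mort, "death"))$p_hip_10y, base)
})

test_that("risk-factor layer multiplies and calibrates as specified", {
  pr0 <- risk_profile(60, "F", bmi = 27)
  expect_equal(adjust_hazard(0.01, pr0, rr_neutral(), "hip"), 0.01)

  rr2 <- relative_risk_model(hip = c(current_smoking = 2))
  pr1 <- risk_profile(60, "F", bmi = 27, current_smoking = TRUE)
  expect_equal(adjust_hazard(0.01, pr1, rr2, "hip"), 0.02)

  # prevalence 0.3: exposed 2h/1.3, unexposed h/1.3, mixture recovers h
  rr3 <- relative_risk_model(hip = c(current_smoking = 2),
                             prevalences = c(current_smoking = 0.3))
  h_exp <- adjust_hazard(0.01, pr1, rr3, "hip")
  h_un <- adjust_hazard(0.01, pr0, rr3, "hip")
  expect_equal(h_exp, 0.02 / 1.3)
  expect_equal(h_un, 0.01 / 1.3)
  expect_equal(0.3 * h_exp + 0.7 * h_un, 0.01)

  # BMI gradient: 5 kg/m2 below reference multiplies by bmi_rr_per_5
  rr4 <- relative_risk_model(bmi_rr_per_5 = c(mof = 1.2, hip = 1.4))
  pr_low <- risk_profile(60, "F", bmi = 22)
  expect_equal(adjust_hazard(0.01, pr_low, rr4, "hip"), 0.014)
  expect_equal(adjust_hazard(0.01, pr_low, rr4, "mof"), 0.012)
})

test_that("turning on a factor with RR > 1 strictly increases both probabilities", {
  tabs <- synthetic_tables()
  rr <- relative_risk_model(mof = c(rheumatoid_arthritis = 1.4),
                            hip = c(rheumatoid_arthritis = 1.9))
  for (age in c(45, 65, 85)) {
    p0 <- ten_year_probability(risk_profile(age, "F"),
                               list(tabs$mof, tabs$hip), tabs$death, rr)
    p1 <- ten_year_probability(risk_profile(age, "F",
                                            rheumatoid_arthritis = TRUE),
                               list(tabs$mof, tabs$hip), tabs$death, rr)
    expect_gt(p1$p_mof_10y, p0$p_mof_10y)
    expect_gt(p1$p_hip_10y, p0$p_hip_10y)
  }
})

test_that("hip probability cannot exceed MOF probability when hip hazard is dominated", {
  tabs <- synthetic_tables()  # ratios > 1 everywhere, so MOF hazard > hip
  for (age in c(40, 60, 80)) {
    res <- ten_year_probability(risk_profile(age, "M"),
                                list(tabs$mof, tabs$hip), tabs$death)
    expect_lte(res$p_hip_10y, res$p_mof_10y)
  }
})

test_that("annual steps are an adequate discretisation of the smooth hazard", {
  tabs <- synthetic_tables()
  pr <- risk_profile(70, "F")
  coarse <- ten_year_probability(pr, tabs$hip, tabs$death)$p_hip_10y
  # same hazards re-evaluated monthly
  t <- seq(70, 80 - 1 / 12, by = 1 / 12)
  fine <- surfrax:::accumulate_decrement(
    hazard_at(tabs$hip, "F", t), hazard_at(tabs$death, "F", t),
    dt = 1 / 12)[["event"]]
  # start-of-year evaluation biases each interval slightly; a few percent
  # relative error against a monthly grid is the expected magnitude
  expect_lt(abs(coarse - fine) / fine, 0.05)
})

test_that("Monte-Carlo oracle is seeded, exact at zero hazard, and matches closed forms", {
  hip <- const_rate_table(1000, outcome = "hip_fracture")  # h = 0.01
  none <- const_rate_table(0, outcome = "death")
  pr <- risk_profile(60, "F")
  a <- monte_carlo_probability(pr, hip, none, n_reps = 2e4, seed = 11)
  b <- monte_carlo_probability(pr, hip, none, n_reps = 2e4, seed = 11)
  expect_identical(a$estimate, b$estimate)
  expect_lt(abs(a$estimate - 0.0951625819640405), 3 * a$se)

  zero <- monte_carlo_probability(pr, const_rate_table(0, outcome = "hip_fracture"),
                                  none, n_reps = 1e3, seed = 2)
  expect_identical(zero$estimate, 0)
})

test_that("closed-form engine agrees with the Monte-Carlo oracle on Gompertz tables", {
  tabs <- synthetic_tables()
  pr <- risk_profile(68, "M", bmi = 25, prior_fracture = TRUE)
  rr <- prior_fracture_rr(1.8)
  eng <- ten_year_probability(pr, tabs$hip, tabs$death, rr,
                              scheme = "step")$p_hip_10y
  mc <- monte_carlo_probability(pr, tabs$hip, tabs$death, rr,
                                n_reps = 5e4, seed = 31)
  expect_lt(abs(eng - mc$estimate), 3 * mc$se)
})
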
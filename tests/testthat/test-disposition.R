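# Impact-sample filtering, per-person classification and the disposition
# summary.

test_that("the impact sample keeps men 50+ and postmenopausal women", {
  cohort <- data.frame(
    id = 1:6,
    sex = c("M", "M", "F", "F", "F", "M"),
    age = c(49, 50, 55, 60, 45, 80),
    postmenopausal = c(NA, NA, TRUE, FALSE, NA, NA))
  expect_warning(kept <- filter_impact_sample(cohort), "menopause status")
  expect_identical(kept$id, c(2L, 3L, 6L))
  expect_identical(nrow(filter_impact_sample(cohort[0, ])), 0L)
})

test_that("classification respects the threshold boundaries (p = IT is eligible)", {
  lat <- 3.51; it <- 7.06; uat <- 8.472
  cls <- function(p, pf = FALSE) {
    as.character(classify_person(p, pf, lat, it, uat))
  }
  expect_identical(cls(1, pf = TRUE), "eligible_prior_fracture")
  expect_identical(cls(3.0), "low_risk")
  expect_identical(cls(lat), "low_risk")          # p <= LAT
  expect_identical(cls(5.0), "bmd_test_recommended")
  expect_identical(cls(it), "eligible_between_it_uat")  # "equalled or exceeded"
  expect_identical(cls(8.0), "eligible_between_it_uat")
  expect_identical(cls(uat), "eligible_between_it_uat")
  expect_identical(cls(9.0), "eligible_high_risk")
  expect_error(classify_person(5, FALSE, 4, 3, 5), "lat <= it <= uat")
})

test_that("eligibility is monotone in the MOF probability", {
  lat <- 3.51; it <- 7.06; uat <- 8.472
  eligible <- c(eligible_prior_fracture = TRUE, low_risk = FALSE,
                bmd_test_recommended = FALSE, eligible_between_it_uat = TRUE,
                eligible_high_risk = TRUE)
  p <- seq(0.5, 12, by = 0.1)
  e <- eligible[as.character(classify_person(p, FALSE, lat, it, uat))]
  expect_true(all(diff(as.integer(e)) >= 0))
})

test_that("categories partition any classifiable cohort exactly", {
  thr <- threshold_table(synthetic_model(prior_fracture_rr(1.8)))
  set.seed(42)
  n <- 300
  cohort <- data.frame(
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 40, 90),
    bmi = runif(n, 18, 35),
    prior_fracture = runif(n) < 0.3,
    p_mof_10y = runif(n, 0, 20))
  cl <- classify_cohort(cohort, thr)
  expect_false(anyNA(cl$category))
  expect_equal(sum(table(cl$category)), n)
  s <- summarize_disposition(cohort, thr)
  for (sx in c("F", "M")) {
    d <- s[s$sex == sx, ]
    cats <- c("prior_fracture", "low_risk", "bmd_test_recommended",
              "between_it_uat", "high_risk")
    expect_equal(sum(d$n[d$group %in% cats]), d$n[d$group == "all"])
    expect_equal(sum(d$pct[d$group %in% cats]), 100)
    expect_equal(d$n[d$group == "eligible_total"],
                 sum(d$n[d$group %in% c("prior_fracture", "between_it_uat",
                                        "high_risk")]))
    expect_equal(d$n[d$group == "bmd_tests"],
                 sum(d$n[d$group %in% c("bmd_test_recommended",
                                        "between_it_uat")]))
  }
  expect_error(classify_cohort(transform(cohort, age = age + 60), thr),
               "threshold table range")
})

test_that("an empty cohort summarises to zero counts", {
  thr <- threshold_table(synthetic_model())
  s <- summarize_disposition(data.frame(), thr)
  expect_true(all(s$n == 0))
  expect_true(all(s$pct == 0))
})

test_that("cohort characteristics reproduce count-percentages and flag degenerate SDs", {
  cohort <- data.frame(sex = rep("M", 403), age = 60, bmi = 26,
                       prior_fracture = c(rep(TRUE, 158), rep(FALSE, 245)))
  ch <- cohort_characteristics(cohort)
  pf <- ch[ch$variable == "prior_fracture", ]
  expect_identical(pf$count, 158L)
  expect_equal(round_half_up(pf$pct, 0), 39)

  expect_warning(one <- cohort_characteristics(
    data.frame(sex = "F", age = 61.3, bmi = 24)), "SD")
  expect_identical(one$sd[one$variable == "age"], 0)
})
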
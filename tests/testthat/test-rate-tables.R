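# Rate-table construction, file round trips, hazard lookup and MOF imputation.

test_that("reading a well-formed file yields a normalised table that round-trips byte-stably", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(f)
  tab <- read_rate_table(f, outcome = "hip_fracture")
  expect_s3_class(tab, "rate_table")
  expect_equal(nrow(tab), 22)
  expect_identical(attr(tab, "outcome"), "hip_fracture")
  expect_false(is.unsorted(tab$age_low[tab$sex == "F"]))

  g <- withr::local_tempfile(fileext = ".csv")
  h <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(tab, g)
  write_rate_table(read_rate_table(g, outcome = "hip_fracture"), h)
  expect_identical(readLines(g), readLines(h))
})

test_that("validation names the offending rows", {
  base <- data.frame(sex = c("F", "F", "M", "M"),
                     age_low = c(50, 55, 50, 55),
                     age_high = c(55, 60, 55, 60),
                     rate = c(10, 20, 10, 20))
  bad <- base
  bad$rate[2] <- -5
  expect_error(rate_table(bad, "hip_fracture"), "rate in row\\(s\\) 2")

  bad <- base
  bad$age_low[2] <- 53  # 50-55 and 53-60 overlap
  expect_error(rate_table(bad, "hip_fracture"), "overlapping")

  bad <- base
  bad$age_low[2] <- 57  # gap 55-57
  expect_error(rate_table(bad, "hip_fracture"), "gap")

  expect_error(rate_table(base[, -4], "hip_fracture"), "missing column")
  expect_error(rate_table(base[base$sex == "F", ], "hip_fracture"),
               "both sexes")
  bad <- base
  bad$age_high[1] <- NA  # open-ended band that is not last
  expect_error(rate_table(bad, "hip_fracture"), "open-ended")
})

test_that("hazard_at converts units, steps on bands and interpolates midpoints", {
  tab <- rate_table(data.frame(sex = rep(c("F", "M"), each = 2),
                               age_low = c(60, 65, 60, 65),
                               age_high = c(65, 70, 65, 70),
                               rate = c(200, 400, 100, 300)),
                    outcome = "hip_fracture")
  # step: band value, converted per person-year
  expect_equal(hazard_at(tab, "F", 62, scheme = "step"), 0.002)
  expect_equal(hazard_at(tab, "F", 64.999, scheme = "step"), 0.002)
  expect_equal(hazard_at(tab, "F", 65, scheme = "step"), 0.004)
  # midpoint_linear: midpoints (62.5, .002) and (67.5, .004) -> age 65 halfway
  expect_equal(hazard_at(tab, "F", 65, scheme = "midpoint_linear"), 0.003)
  # flat extrapolation outside the outermost midpoints
  expect_equal(hazard_at(tab, "F", 30, scheme = "midpoint_linear"), 0.002)
  expect_equal(hazard_at(tab, "F", 95, scheme = "midpoint_linear"), 0.004)
  expect_error(hazard_at(tab, "X", 62), "unknown sex")
})

test_that("step hazards are non-negative, piecewise constant within bands", {
  tabs <- synthetic_tables()
  ages <- seq(40, 99, by = 0.25)
  for (s in c("F", "M")) {
    h <- hazard_at(tabs$hip, s, ages, scheme = "step")
    expect_true(all(h >= 0))
    # constant inside each 5-year band
    for (lo in seq(40, 85, by = 5)) {
      inside <- ages >= lo & ages < lo + 5
      expect_equal(length(unique(h[inside])), 1)
    }
    expect_true(all(hazard_at(tabs$hip, s, ages) >= 0))  # midpoint scheme too
  }
})

test_that("MOF imputation multiplies by the matching ratio and preserves structure", {
  hip <- const_rate_table(120, 120, outcome = "hip_fracture")
  ratios <- ratio_table(data.frame(sex = c("F", "M"), age_low = 40,
                                   age_high = NA, ratio = 4.5))
  mof <- impute_mof_incidence(hip, ratios)
  expect_identical(attr(mof, "outcome"), "mof")
  expect_equal(mof$rate, c(540, 540))

  # identity ratios leave rates unchanged; zero hip stays zero
  tabs <- synthetic_tables()
  ones <- tabs$ratios
  ones$ratio[] <- 1
  expect_equal(impute_mof_incidence(tabs$hip, ones)$rate, tabs$hip$rate)
  zero <- tabs$hip
  zero$rate[3] <- 0
  zero <- rate_table(as.data.frame(zero), "hip_fracture")
  expect_equal(impute_mof_incidence(zero, tabs$ratios)$rate[3], 0)

  # band structure and sex set preserved exactly
  mof2 <- impute_mof_incidence(tabs$hip, tabs$ratios)
  expect_identical(as.data.frame(mof2)[, c("sex", "age_low", "age_high")],
                   as.data.frame(tabs$hip)[, c("sex", "age_low", "age_high")])

  # band mismatch is an error
  short <- ratio_table(data.frame(sex = c("F", "M"), age_low = 40,
                                  age_high = 45, ratio = 2))
  expect_error(impute_mof_incidence(tabs$hip, short), "band structure")
  expect_error(impute_mof_incidence(tabs$mof, tabs$ratios), "hip_fracture")
})
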
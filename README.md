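# surfrax

Surrogate country fracture-risk models with competing mortality.

Many countries request FRAX-style fracture risk assessment but have no
fracture register of their own. The accepted remedy is a **surrogate
model**: borrow age- and sex-specific hip-fracture incidence from a
neighbouring country where rates are thought representative, keep the index
country's own all-cause mortality, and impute the incidence of the other
major osteoporotic fractures (MOF: hip, clinical spine, distal forearm,
proximal humerus) from hip incidence via register-derived MOF:hip ratios.
`surfrax` implements that construction end to end for epidemiologists and
guideline developers: the probability engine, the treatment thresholds
built on it, the classification of a referral cohort against those
thresholds, and the projection of the national hip-fracture burden as the
population ages.

## The model

For a person of age *a* and sex *s*, the 10-year probability of fracture
accounts for the competing risk of death. With piecewise-constant annual
hazards — fracture incidence *h*(t) (scaled to the individual by the
clinical-risk-factor layer) and all-cause mortality *μ*(t) — the engine
accumulates, over one-year intervals *j* = 0, …, 9,

```
P(fracture within 10y) = Σ_j  S_j · h_j/(h_j+μ_j) · (1 − exp(−(h_j+μ_j))),
S_j = exp(−Σ_{k<j} (h_k + μ_k))
```

the classical double-decrement computation: in each year the event
competes with death, and only event-free survivors carry into the next
year. Individual risk scales the population hazard by
`RR(profile)/RR(population)`, where `RR(profile)` multiplies per-factor
relative risks over the seven clinical risk factors (prior fracture,
parental hip fracture, current smoking, glucocorticoids, rheumatoid
arthritis, secondary osteoporosis, alcohol ≥ 3 units/day) and a BMI
gradient; the denominator makes the population average reproduce the
published incidence. The relative risks are a *configurable layer* — the
true FRAX coefficients are proprietary and include age dependence and
interactions this package deliberately does not claim to reproduce.

On top of the engine:

* **Thresholds** — the age-specific intervention threshold (IT) is the MOF
  probability of a woman with a prior fragility fracture, no other risk
  factors, BMI 27 kg/m²; the lower assessment threshold (LAT) is the same
  woman without the fracture; the upper assessment threshold is
  UAT = 1.2 × IT.
* **Disposition** — men 50+ and postmenopausal women are classified as
  prior-fracture (eligible outright), low risk (≤ LAT), BMD test
  recommended (LAT–IT), eligible (≥ IT), or high risk (> UAT).
* **Projection** — stable incidence applied to population pyramids gives
  expected annual hip fractures and their calendar-time increase.
* **Synthetic data** — seeded generators for referral cohorts, Gompertz
  (log-linear in age) hazard tables and ageing pyramids, so the whole
  pipeline is testable without any restricted data.

## Worked example

```r
library(surfrax)

tabs  <- generate_rate_tables()             # synthetic Gompertz hazards
rr    <- read_rr_model(system.file("extdata", "rr_placeholder.yaml",
                                   package = "surfrax"))
model <- frax_surrogate(tabs$hip, tabs$death,
                        mof_ratios = default_ratio_table(), rr_model = rr)

predict(model, data.frame(age = 65, sex = "F", bmi = 24,
                          prior_fracture = TRUE), percent = TRUE)
#>   p_mof_10y p_hip_10y survival_10y
#> 1   11.2155  2.341814     84.48926

threshold_table(model, ages = seq(50, 70, 10))
#>  age lat_mof it_mof uat_mof lat_hip it_hip uat_hip
#>   50    2.26   4.04    4.85    0.26   0.46    0.55
#>   60    4.41   7.79    9.35    0.67   1.21    1.45
#>   70    7.20  12.56   15.07    1.67   2.99    3.59
```

A 65-year-old woman with a prior fracture and BMI 24 has an 11.2% 10-year
MOF probability and 2.3% hip probability on these synthetic hazards; her
84.5% 10-year survival is what makes the probabilities smaller than the
naive cumulative incidence. In the threshold table each row is one age:
e.g. at 60 a BMD test is indicated between 4.41% and 9.35% MOF
probability, and treatment from 7.79% upward. Classifying a generated
referral cohort:

```r
cohort <- filter_impact_sample(generate_cohort(seed = 42))
s <- summarize_disposition(cohort, threshold_table(model), model = model)
s[s$group %in% c("all", "prior_fracture", "eligible_total", "bmd_tests"), ]
#>  sex          group   n   pct mean_p_mof mean_bmi
#>    F            all 321 100.0        7.5     27.3
#>    F prior_fracture 108  33.6       10.6     27.2
#>    F eligible_total 138  43.0       10.6     26.3
#>    F      bmd_tests 142  44.2        5.9     26.2
#>    M            all 259 100.0        4.4     26.5
#>    M prior_fracture  93  35.9        6.4     26.7
#>    M eligible_total  95  36.7        6.4     26.7
#>    M      bmd_tests  37  14.3        4.8     23.7
```

Reference tables for the published Mongolian surrogate model (age-specific
LAT/IT/UAT, eligibility-cohort counts, and the 2015–2050 hip-fracture
projection) ship under `inst/extdata/` and are used by the acceptance
checks below. A thin command-line wrapper with `thresholds`, `classify`,
`project` and `simulate` subcommands lives at `inst/cli/surfrax.R`.

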
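Package: surfrax
Title: Surrogate Country Fracture-Risk Models with Competing Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and application of surrogate country fracture-risk
    models in the FRAX tradition. Computes 10-year probabilities of hip and
    major osteoporotic fracture under the competing risk of death from age-
    and sex-specific incidence and mortality tables, imputes major
    osteoporotic fracture incidence from hip-fracture incidence via fixed
    ratios, derives age-dependent intervention and assessment thresholds,
    classifies referral cohorts for treatment eligibility, and projects
    hip-fracture burden under demographic change. Ships seeded generators
    for synthetic cohorts, Gompertz-like hazard tables and ageing population
    pyramids, plus a Monte-Carlo validation oracle for the probability
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
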
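# Placeholder clinical-risk-factor configuration.
#
# CAVEAT: the relative risks below are literature-style illustrative values
# chosen to have plausible magnitudes and orderings. They are NOT the FRAX
# coefficients, which are proprietary and include age-dependence and
# interactions this layer deliberately does not model. Edit freely; nothing
# in the package's validation depends on these magnitudes.
bmi_reference: 27
bmi_rr_per_5:
  mof: 1.2
  hip: 1.4
relative_risks:
  mof:
    prior_fracture: 1.8
    parent_hip_fracture: 1.5
    current_smoking: 1.1
    glucocorticoids: 1.6
    rheumatoid_arthritis: 1.4
    secondary_osteoporosis: 1.4
    alcohol_3plus: 1.4
  hip:
    prior_fracture: 1.8
    parent_hip_fracture: 2.3
    current_smoking: 1.6
    glucocorticoids: 2.0
    rheumatoid_arthritis: 1.9
    secondary_osteoporosis: 1.9
    alcohol_3plus: 1.7
population_prevalences:
  prior_fracture: 0.25
  parent_hip_fracture: 0.15
  current_smoking: 0.20
  glucocorticoids: 0.04
  rheumatoid_arthritis: 0.03
  secondary_osteoporosis: 0.08
  alcohol_3plus: 0.06
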
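---
title: "Surrogate fracture-risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate fracture-risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfrax)
```

## The problem

FRAX-style tools report the 10-year probability of hip fracture and of any
major osteoporotic fracture (MOF) from a handful of clinical risk factors.
Building such a model needs two hazard schedules the index country often
lacks in part: age/sex-specific fracture incidence and all-cause mortality.
A *surrogate* model keeps the index country's mortality (which national
statistics always provide) and borrows hip-fracture incidence from a
neighbouring country. Because registers rarely capture non-hip fractures
completely, MOF incidence is imputed from hip incidence through fixed
MOF:hip ratios taken from registers with full ascertainment. `surfrax`
implements this construction, the treatment thresholds defined on it, the
classification of a referral cohort, and the demographic projection of the
hip-fracture burden.

## The probability engine

### Double-decrement accumulation

Fracture and death are competing decrements. Over a one-year interval with
constant event hazard $h$ and death hazard $\mu$, the probability that the
event occurs first is

$$\frac{h}{h+\mu}\left(1 - e^{-(h+\mu)}\right),$$

and the interval's event-free survivors, $e^{-(h+\mu)}$, carry
multiplicatively into the next year. Ten such intervals, with hazards
re-evaluated at each interval's start age, give the 10-year probability.
The decomposition *event + death-first + event-free = 1* holds exactly by
telescoping, and the test suite asserts it to $10^{-12}$.

**Why one-year steps?** Annual intervals are the life-table convention and
match the resolution of the input tables. The discretisation error of
evaluating a smoothly rising hazard at the interval start, rather than
integrating it, is a few percent relative on the final probability for
steep Gompertz hazards (the suite compares against a monthly grid and
bounds the relative difference at 5%). Since every threshold is defined
*through the same engine*, this bias cancels in all comparisons the package
makes; it matters only if outputs are compared against an engine with a
different step rule.

### Hazards from banded rates

Rates arrive per 100,000 person-years on half-open 5-year bands
$[a, a+5)$, the last band open-ended; they are stored exactly as read and
converted to per-person-year hazards only at evaluation. Two schemes are
exposed:

* `step` — the band value, piecewise constant. Used by the Monte-Carlo
  oracle and the burden projection, where the band is the natural unit.
* `midpoint_linear` (default) — rates anchored at band midpoints, linear
  between midpoints, flat beyond the outermost midpoints. Probabilities
  quoted at exact ages (40, 45, …) imply a smooth age trend; the midpoint
  anchoring preserves each band's level while avoiding staircase
  artefacts. The open-ended top band is assigned the width of the
  preceding band for its midpoint.

The choice is a model argument because published engines do not document
their interpolation; both schemes satisfy the same monotonicity and
decomposition properties.

### The clinical-risk-factor layer

The published FRAX coefficients are proprietary. The package therefore
exposes a transparent multiplicative stand-in: per-factor relative risks
per outcome, and a BMI gradient $r^{(\mathrm{BMI_{ref}}-\mathrm{BMI})/5}$
anchored at a reference BMI of 27 kg/m² (a typical referral-cohort mean).
Individual hazards are the population hazard times
$\mathrm{RR(profile)}/\mathrm{RR(population)}$, where the denominator
$\prod_f (p_f \mathrm{RR}_f + 1 - p_f)$ uses configured factor prevalences
so that a population with those prevalences reproduces the incidence table
on average — without this calibration, applying relative risks above 1 to
everyone would inflate the population burden. The shipped
`rr_placeholder.yaml` carries literature-style magnitudes and a prominent
caveat; every validation in the package either uses the neutral layer or
tests structural properties (ordering, monotonicity, calibration
identities), never the placeholder magnitudes. Known simplifications: no
age-dependence of relative risks, no interactions, no BMD term (the layer
targets cohorts assessed without femoral-neck BMD), no post-fracture
excess mortality (the death hazard is the all-cause table throughout).

### The Monte-Carlo oracle

`monte_carlo_probability()` validates the engine by a route that shares no
algebra with it: within each year it draws competing exponential event and
death times at the step-scheme hazards and records which, if either, lands
inside the year. Agreement within three binomial standard errors at
200,000 replicates — checked across twelve (profile, table) scenarios with
both sexes, three ages and two Gompertz steepnesses — ties the analytic
accumulation to a direct simulation of the stochastic process. The
replicate count is chosen so the Monte-Carlo standard error (≈0.05% on a
5% probability) resolves discrepancies well below clinical relevance while
keeping the full grid to seconds of runtime.

## Thresholds

The intervention threshold (IT) at each age is the engine's MOF output for
a woman with a prior fragility fracture, no other factors, BMI 27; the
lower assessment threshold (LAT) is the same profile without the fracture;
the upper assessment threshold (UAT) is $1.2\times$IT, the factor beyond
which additional BMD information rarely reclassifies a patient. Hip
thresholds are the hip-probability outputs of the *same* defining
profiles, with hip UAT $=1.2\times$ hip IT likewise. All three are kept at
full precision internally; printing rounds half-up to two decimals, the
convention of published threshold tables. One printed reference row (the
age-40 hip UAT in the shipped Mongolian reference table) does not equal
1.2 times its printed IT under any rounding; the package follows the
stated rule and the acceptance checks exclude that single cell rather than
reverse-engineer an undocumented exception.

Under a neutral risk-factor layer IT collapses onto LAT; with any
prior-fracture relative risk above 1, LAT < IT < UAT strictly at every age
— both directions are tested.

## Cohort disposition

Eligibility is assessed in men aged 50+ and postmenopausal women. The
menopause flag is an explicit input column, not an age proxy: it is an
eligibility criterion with no published imputation rule, so inferring it
would silently change denominators. Each person then falls in exactly one
category: prior fracture (eligible outright); $p \le$ LAT low risk;
LAT $< p <$ IT BMD test recommended; IT $\le p \le$ UAT eligible with BMD
still informative; $p >$ UAT eligible at high risk. The boundary $p =$ IT
is *eligible*: the defining wording ("equalled or exceeded") wins over
table labels that draw the line the other way, and the conflict affects
only measure-zero boundary cases. Threshold values at non-grid ages are
linearly interpolated from the threshold table; ages outside the table are
an error rather than an extrapolation. Derived aggregates follow the
published convention: eligible = prior fracture + high risk + between
IT and UAT; BMD tests = everyone with LAT $< p \le$ UAT.

## Burden projection

Expected annual fractures are $\sum \text{rate}/10^5 \times \text{head
count}$ over bands at or above age 50, by sex — head counts approximate
person-years for an annual snapshot, which is as fine as the method's
inputs justify. The calendar series reports `increase_index`
$= 100 \times \text{total}_y / \text{total}_{\text{base}}$: published
projection tables print this *ratio index* (base year = 100), not a
percent change, and the field name says so to prevent the 120-vs-20
misreading. Band alignment between pyramid and incidence table is enforced
exactly; whether single-year or 5-year bands are used is therefore decided
by the inputs, not the code.

## Synthetic data

The generators emulate the statistical structure the analysis assumes:

* **Cohorts** — ages truncated-normal on [40, 90] (referral studies
  recruit from 40; 90 is the engine's upper age), BMI truncated-normal
  above 14 kg/m², seven independent Bernoulli risk factors, and a
  postmenopausal flag drawn from a logistic curve in age crossing 0.5 at
  age 50 with a 2.5-year scale (a conventional menopause-age model; the
  parameters are configurable). The default specification reflects a
  referral population: ~400 per sex, men near age 52 (SD 10) with high
  smoking and alcohol prevalence, women near 54 with roughly a third
  carrying a prior fracture. Truncation shifts sample moments away from
  the parent parameters (for a parent mean 51.6, SD 10.4 truncated at 40,
  the truncated mean is ≈54.2, SD ≈8.5); recovery tests therefore compare
  sample moments against the closed-form truncated-normal moments of the
  generating law, the only comparison that is consistent at any truncation
  strength.
* **Hazard tables** — Gompertz-like: rate = baseline ×
  exp(slope × (midpoint − 50)) per 100,000 person-years. Defaults give hip
  incidence near 25–30/100k at 50 rising roughly tenfold by 75, and
  mortality a few hundred per 100k at 50 (higher in men) reaching ~10%/yr
  by 90 — realistic orders of magnitude for an East Asian setting, though
  deliberately *not* any specific country's published schedule.
* **Pyramids** — per-band compound growth; old-band growth above
  young-band growth emulates a medium-variant ageing projection.

What passing tests on these inputs show: the arithmetic, orderings,
calibration and competing-risk behaviour of every pipeline stage. What
they cannot show: that any particular country's incidence is well
approximated by its neighbour's (the surrogate assumption itself, untestable
without a register), correlations among risk factors (generated
independently; the `cohort_spec` object leaves room for a correlation
structure),
or the magnitudes of the true FRAX coefficients.

## Numerical conventions

* Rounding for printed tables is half-up (ties away from zero): two
  decimals for probabilities, one for percentages, integers for projected
  counts — matching how such tables are published. `round_half_up()` is
  exported because reproducing printed values with IEEE round-half-even
  fails on exact ties.
* All stochastic entry points (`generate_cohort()`,
  `monte_carlo_probability()`, `simulate()`) require or accept a seed,
  restore the caller's RNG state, and are bit-reproducible under a fixed
  seed.
* Degenerate inputs: zero hazards propagate to exact zeros; an empty
  cohort summarises to zero counts with percentages reported as 0; a
  single-record stratum reports SD 0 with a warning; validation errors
  name the offending rows.

## Problem sizes

The shipped validation uses 200,000 Monte-Carlo replicates per scenario
(twelve scenarios), cohorts of ~400 per sex for recovery checks, and
4,000-person cohorts where distributional shape is examined — sizes at
which binomial and moment standard errors are small enough to make the
3-SE checks meaningful while the whole suite runs in well under a minute.

## Known limitations

The relative-risk layer is an explicit approximation, not FRAX; BMD-adjusted
probabilities are out of scope; post-fracture excess mortality is not
modelled; MOF:hip ratios are an input whose provenance the user must judge;
and the surrogate assumption — that the donor country's incidence
represents the index country — is exactly that, an assumption.
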
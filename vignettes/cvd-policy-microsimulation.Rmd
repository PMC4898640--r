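---
title: "Modelling primary CVD prevention policies with cvdmicrosim"
author: "cvdmicrosim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling primary CVD prevention policies with cvdmicrosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cvdmicrosim` is a discrete-time dynamic stochastic microsimulation of
primary prevention of cardiovascular disease (CVD), defined here as
first-ever coronary heart disease (CHD) plus first-ever stroke. It
simulates the annual life course of synthetic adults aged 30-84 with
socioeconomic structure (fifths of an area deprivation index, fifth 1 the
least deprived), projects the horizon 2011-2030, and compares five policy
scenarios: continuation of current trends (baseline), universal
risk-score-based screening of 40-74 year olds, screening concentrated in
the two most deprived fifths, a structural population-wide diet and
smoking intervention, and the combination of the population-wide
intervention with concentrated screening. This vignette documents the
model, its assumptions and the design choices a maintainer should know
about.

## The disease model

Each person carries a current exposure profile - body mass index (BMI,
kg/m²), systolic blood pressure (SBP, mm Hg), total cholesterol (mmol/L),
diabetes, smoking status (never/former/current) with years since
quitting, environmental tobacco smoke, daily fruit and vegetable
portions, and weekly physical-activity days - plus a five-year lag buffer
of past profiles. Incidence in year $y$ is driven by the exposures of
year $y-5$: a five-year lag between exposure and disease is assumed
throughout, which is why interventions starting in 2011 first affect
event counts in 2016.

Exposures combine multiplicatively. For person $i$ and disease $d$:

$$\mathrm{RR}_{id} = \prod_{k}\ \max\!\left\{rr_{kd}^{\,(x_{ik} - x_k^{\mathrm{ref}})/u_k},\ 0.5\right\}
  \quad\text{(continuous)}\ \times\ \prod_{m} rr_{md}[x_{im}]\quad\text{(categorical)},$$

where $u_k$ is the unit size of the published effect (e.g. 20 mm Hg SBP)
and the per-factor floor of 0.5 guards against implausible protective
extrapolation far below reference. The multiplicative-risk assumption is
the status quo of comparative risk assessment; it is a simplification and
is listed under limitations. The shipped relative risks
(`default_relative_risks()`) are literature-plausible editable defaults
with 95% intervals used for second-order sampling - they are
configuration, not findings.

Annual incidence probabilities are anchored to configured stratum rates by
calibration: within each age band x sex stratum,
$p_0 = \text{rate} / \overline{\mathrm{RR}}$, so the population-expected
incidence equals the configured rate exactly (to numerical precision).
Calibration runs once per Monte Carlo iteration on the first simulated
year's population and is shared by all scenarios of that iteration, so an
intervention that lowers exposures is never "re-calibrated away".

Death competes across three causes. Disease deaths require the disease:
an incident case dies in its first year with the stratum case fatality;
prevalent cases face an annual excess mortality of case fatality x 0.35
(an editable default; the within-year survival structure of prevalent
disease is not specified by the published scenario assumptions, so the
package states its own convention). Case fatality improves 3% relatively
per year and worsens multiplicatively by 1.05 per deprivation fifth
beyond the middle fifth; risk factors never modify case fatality, only
incidence. Other-cause mortality follows a Gompertz-shaped life-table
analogue with the same deprivation gradient. Within a year the single
death draw resolves on the cumulative scale in the fixed order
other-cause, CHD, stroke.

## The synthetic population

`default_population_spec()` describes an England-like population around
2011: five-year age bands 30-34 ... 80-84 with weights declining at older
ages, equal sexes, and equal 20% deprivation fifths. Each risk factor has
a linear-predictor mean (intercept, age, sex, deprivation terms), a
spread, an annual secular trend slope (linear on the natural scale for
continuous factors, linear on the log-odds scale for prevalences - the
simplest shapes consistent with continuing observed trends, with log-odds
keeping prevalences in (0,1)), and hard plausibility bounds. Defaults
continue the direction of 2001-12 trends: BMI and diabetes rising, SBP,
cholesterol and smoking falling. Exposures are drawn independently
*conditional on* age band, sex and deprivation fifth; the stratification
already induces realistic marginal clustering, and no copula is imposed.

The generator emulates survey-like structure - gradients, trends,
realistic magnitudes - but not everything about real data: it has no
household structure, no geography beyond the deprivation label, no
migration or social mobility (an open cohort: persons exiting at 85 are
replaced by new 30-year-old cohorts), and individual trajectories evolve
only through the secular slopes, not through age-period-cohort dynamics.
Passing tests therefore demonstrate internal validity of the machinery
and calibration, not predictive validity for England; the
`compare_to_observed()` operation exists so users can confront simulated
CVD deaths with a real observed series.

Build-time exposures represent the year before the first simulated year,
and lag buffers are back-cast 1-5 further years along the trends, so that
the first simulated year already has a complete five-year history.

## Screening and treatment

Eligibility follows the national health-check programme: ages 40-74, no
known CVD, no diabetes (the remaining exclusion morbidities are not
modelled; a configurable exclusion fraction, default 0, stands in).
Uptake is 50%. The participant mix is calibrated to the observed
programme: 70% of participants below 10% ten-year risk, 25% between 10
and 20%, 5% at 20%+, and 30% of participants older than 60. Selection
performs iterative proportional fitting of the (risk band x over-60)
target table against the eligible pool and samples within cells; when the
pool cannot support the targets the closest feasible mix is used with a
logged warning. Concentrated screening instead samples participants whose
risk and age distribution matches its (more deprived) eligible pool.

Ten-year risk is a simplified Cox-style score,
$1 - S_0^{\exp(\beta'x)}$, with editable coefficients
(`default_risk_coefficients()`) spanning age, SBP, cholesterol, smoking,
diabetes, BMI and deprivation. The exact published screening score (with
its fractional polynomials and interactions) is out of scope: what drives
the simulation is band membership, and bands are recalibrated during
selection anyway. The default coefficients were chosen once so that the
England-like eligible pool supports the calibrated participant mix with
plausible risk gradients.

Participants above the 10% treatment threshold receive: statins with
probability 0.24 (risk >= 20%) or 0.17 (10-20%) if cholesterol >= 5
mmol/L; antihypertensives with probability 0.27 / 0.20 if SBP >= 135 mm
Hg; bariatric surgery if BMI > 50 (BMI set to 30); lifestyle counselling
(BMI x 0.99 once; +1 fruit/veg portion with probability 0.5 if below 5;
+1 active day with probability 0.5 if below 5); and a 10% one-year
smoking-cessation rate with relapse following a general-population
schedule declining in years since quitting (0.30, 0.20, 0.10, then
0.05/year - an editable stand-in for external relapse sources). Drug
effects (default 1.3 mmol/L cholesterol, 10 mm Hg SBP - editable
stand-ins for published effect sizes) are scaled by 70% adherence and
persist with probability 0.80 beyond the first year, drawn once per
person; discontinuers revert to their counterfactual trajectories because
drug effects are overlaid on the stored natural trajectory rather than
mutating it. Lifestyle changes persist indefinitely (the evidence is
silent; a decay option would be a configuration extension). High-risk
status is assigned once at screening; participants are not re-scored
annually.

## The population-wide intervention

Phased with the same diffusion schedule: the annual BMI trend increment is
damped 5%; mean SBP falls by 0.8 mm Hg; half the population gains one
daily fruit/vegetable portion (responders flagged once); and current
smokers quit with annual hazard $1-(1-0.13)^{1/5}$ during diffusion so
prevalence falls 13% relatively over five years. Structural quits are
modelled as quitting by adults (not prevented initiation, since the
simulated cohort is 30+) and do not relapse, unlike cessation-programme
quits - the prevalence target is a net population outcome.

## Scenario machinery and the within-year order

All interventions begin in 2011 and diffuse linearly over five years;
`coverage()` uses the convention that the first year delivers 1/5 of the
full effect (2011 -> 0.2, 2015 -> 1.0), isolated in one function because
the phrase "diffused over five years" is ambiguous about the first-year
value. Screening recruits each year from the never-screened eligible pool
at rate uptake/5, which reaches the target uptake across the diffusion
period and then continues as a rolling programme; re-screening of past
participants is off by default.

The fixed sub-steps of a simulated year are: (1) secular trend advance
and lag-buffer push of the previous year's *effective* (treated)
exposures; (2) policy actions for the year - relapse, recruitment,
treatment assignment and effects, population-policy flags; (3) event
probabilities from the five-year-lagged exposures; (4) competing-risk
draws; (5) stratified recording; (6) aging, exit above 84, entry of new
30-year-olds. Advancing before applying policy means an intervention
applied in year $y$ enters the buffer at the $y+1$ push and reaches the
five-year slot in $y+5$ - exactly the stated lag (2011 interventions
first matter in 2016). Applying policy before the advance would have
shortened the lag by one year, contradicting the lag assumption, which is
why this order was chosen.

## Uncertainty design

Second-order Monte Carlo: each iteration draws one synthetic population
and one set of parameters (each relative risk from a log-normal implied
by its 95% interval), then runs every scenario against them.
First-order event randomness uses *common random numbers*: each
(iteration, year) has a matrix of uniforms indexed by person id, and
every Bernoulli event consumes its person's uniform. Scenario
differences therefore isolate intervention effects; a policy with zero
uptake reproduces the baseline cube bit for bit, and concentrated
screening leaves the undeprived fifths' counts exactly unchanged.
Policy-internal randomness (who is recruited, who persists) uses separate
per-scenario streams so it cannot desynchronise the event draws.

Results are summarised by medians and interquartile ranges (first/third
fourths) across iterations, with quartiles by linear interpolation
between order statistics (`stats::quantile` type 7) - a fixed convention
for reproducibility. Equity indices are always computed per iteration and
then summarised, never index-of-medians. The package default of 200
iterations stabilises reported medians; the shipped tests use 50
iterations on 10 000-person populations, problem sizes chosen to keep a
full five-scenario experiment in the minutes range on a laptop while
leaving the orderings of interest well resolved.

## Effectiveness and equity metrics

Cases (or deaths) prevented or postponed (CPP/DPP) are per-iteration
differences of cumulative 2016-2030 counts, baseline minus scenario; they
can be negative in individual iterations. The absolute equity slope
index regresses CPP per deprivation fifth on the fractional-rank
midpoints 0.1, 0.3, 0.5, 0.7, 0.9 (least to most deprived; equal
population fifths make these the standard slope-index-of-inequality
regressor) and reports the OLS slope, positive when deprived fifths gain
more. The relative index first divides each fifth's CPP by its baseline
burden (x100) and regresses those percentages, so it is positive when the
intervention reduces *relative* inequality. The equity summary chart
plots total CPP against the absolute index; its "equity curve" is the
locus generated by allocating a total CPP proportionally to baseline
burden shares - allocations on the curve leave relative inequality
unchanged, points above reduce it. The curve is linear in the total by
construction.

## Numerical choices and degenerate inputs

* Baseline calibration caps $p_0 \cdot \max(\mathrm{RR})$ at 1 with a
  warning rather than emitting probabilities above 1.
* If cause-of-death probabilities ever sum above 1 they are renormalised
  (counted in the run log); with the shipped defaults this does not occur.
* Continuous exposures are clamped to their specification bounds at
  generation, after every trend step, and when treated overlays are
  pushed into the lag buffer.
* Categorical prevalence-shift transitions use the theoretical
  (specification) prevalence trajectory at the person's current age, so
  transition probabilities are scenario-independent and common random
  numbers remain exact.
* Empty populations, zero-uptake policies and zero-coverage years are
  no-ops, not errors.
* Seeds: one master seed; per-iteration, per-module and per-year
  sub-streams are derived with a deterministic integer mix, all below
  2^31.

## Shipped defaults and their provenance

The default incidence, case-fatality and other-cause mortality tables are
Gompertz/logistic shapes on age chosen so that the baseline scenario at
desk scale reproduces an England-scale burden (about 420 first-ever CVD
cases and 160 CVD deaths per 10 000 adults aged 30-84 over 2016-2030, the
magnitude reported for the full population by national statistics-based
models). They are synthetic stand-ins for rate tables a user would derive
from registry data, and every value is replaceable through
`dump_defaults()` and the YAML/CSV configuration surface.

## Known limitations

Multiplicative risk combination ignores exposure interactions; risk
factors do not affect case fatality (only primary prevention is
modelled); no secondary prevention, recurrence or atrial-fibrillation
detection; no migration, social mobility or socioeconomic consequences of
disease; lifestyle effects persist without decay; screening exclusion
morbidities beyond diabetes are approximated by a configurable fraction.
Most of these biases act on all scenarios alike, so scenario
*differences* are more trustworthy than absolute projections.
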
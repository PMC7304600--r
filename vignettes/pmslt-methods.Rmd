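---
title: "Methods: the pmslt policy evaluation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pmslt policy evaluation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

# Overview

`pmslt` evaluates population-level obesity prevention policies against a
no-intervention comparator in three stages: (1) the intervention's effect
size is translated into per-stratum risk-factor changes (BMI and/or
physical-activity band occupancy); (2) potential impact fractions (PIFs)
scale disease incidence inside a proportional multi-state life table
(PMSLT) Markov cohort model, yielding discounted health-adjusted life
years (HALYs) and healthcare cost offsets; (3) intervention costs, ICERs,
dominance classes, league tables and uncertainty intervals summarise the
economics. This vignette records the model's assumptions, its tunable
parameters, the numerical choices, and what the synthetic data do and do
not emulate.

# The population and its closed cohorts

The modelled population is a cross-section of single-year age (2–100) by
sex strata observed at a 2010-style reference year. Each stratum is a
closed cohort: no births, no migration; it ages until 100 or extinction,
and is truncated at age 100 with its final (half-cycle-corrected)
person-years counted. Per stratum the bundle carries the cohort size, a
log-normal BMI distribution (`bmi_mu`, `bmi_sigma` on the log scale),
prevalences over four ordered physical-activity bands (inactive, low,
moderate, high; band midpoints 0/300/900/1800 MET-min per week), mean
height, all-cause mortality, and an all-cause background morbidity (YLD)
rate.

BMI is modelled as log-normal: positivity and right skew are the
dominant features of adult BMI distributions, and the distribution-shift
PIF only needs a density with a location shift. Physical activity is
categorical because the relative-risk evidence it consumes is
categorical; nothing finer is identifiable from such RRs.

# Effect translation

* **kJ/day → kg.** Sustained intake changes map to steady-state weight
  change through a linear coefficient: ΔW = ΔE/ρ with ρ_adult = 94 and
  ρ_child = 100 kJ/day per kg (configurable under `energy_balance`).
  A full dynamic energy-balance model would produce a weight trajectory;
  the model is annual-cycle and applies the steady-state level shift from
  the first year, so the linear coefficient is an explicit, documented
  stand-in.
* **kg → BMI.** ΔBMI = ΔW/h² at the stratum's mean height.
* **BMI z → BMI (children).** The LMS transform
  BMI(z) = M·(1 + L·S·z)^(1/L) (M·e^{S·z} at L = 0), evaluated at the
  child's age and sex; z is restricted to [−4, 4].
* **MET-min/week → kJ/day.** ΔE = MET-min × mass × 0.0175 kcal/(kg·MET-min)
  × 4.184 kJ/kcal / 7. Gross MET-minutes are converted by default; the
  `net_mets` flag removes resting expenditure assuming activity at
  4 METs. Activity effects also shift BMI (the energy deficit is assumed
  uncompensated) unless `pa_affects_bmi` is off, and move
  `uptake × scale × min(1, effect/600)` of each band's mass one band
  upward — a deliberately simple one-step mechanism, since the evidence
  base never resolves the full transition matrix.

Effects are scaled by uptake and by the maintenance profile: `sustained`
(regulatory-style, maintained for the lifetime of the population),
`step_to_zero(E)`, or `linear_decay(E)` (full effect through the
implementation years, then linear to zero at year E). Targeting is by age
at model start; a cohort keeps its delta as it ages while the effect
lasts.

# Potential impact fractions

For BMI the distribution-shift method is used:
PIF = 1 − E₁[RR(X)]/E₀[RR(X)] with RR(x) = RR^max(0, x − TMREL) and the
shifted density f₁(x) = f₀(x − δ), i.e. a translation on the natural
scale with sigma preserved. The RR is per BMI unit above the
theoretical-minimum-risk exposure level (TMREL, 21–23 kg/m² in the
default catalogue). Integration is composite trapezoid on 2001 nodes over
[10, 60] kg/m² with a node placed exactly at the TMREL kink; the bulk
path used inside scenario evaluation reuses the cached baseline density
through a change of variables (the kink then falls between nodes; the
O(Δx²) discrepancy against the exact-node operation is ~3×10⁻⁷ and is
covered by a cross-path test). Distributions whose mass would leave the
grid raise an error rather than integrate silently.

For physical activity the relative-risk-shift method is used over the
band prevalences, and for the five diseases related to both risk factors
the two PIFs combine multiplicatively. PIFs scale *incidence only* —
never case fatality or remission — and negative PIFs (harmful shifts)
propagate unchanged.

# The proportional multi-state life table

Each disease runs as a parallel susceptible/prevalent sub-lifetable with
annual cycles. Within a cycle the update order is fixed: incidence (scaled
by 1 − PIF), case fatality, remission, then background mortality. Rates
become probabilities via q = 1 − exp(−rate), which keeps compartments
non-negative. Background mortality removes mass proportionally from both
compartments, so it cancels from the conditional prevalence C/(S + C) and
the sub-lifetables omit it. Cohorts start at their 2010 age with the
steady-state prevalence obtained by running the same recursion from the
youngest modelled age — which makes the baseline main-lifetable mortality
equal the bundled all-cause mortality exactly, and makes a null scenario
(PIF ≡ 0) reproduce baseline to machine precision.

The main lifetable uses m = residual mortality + Σ_d prevalence_d × case
fatality_d, with residual mortality = all-cause − implied disease
mortality (floored at zero with a warning). Morbidity is the baseline YLD
rate adjusted by Σ_d ΔC_d × disability weight_d (additive comorbidity,
capped at 1), plus the child HRQoL term: a utility decrement of
`child_hrql_coeff` (default 0.005, configurable) per BMI unit above the
age–sex growth-reference median for ages 2–17, applied in baseline and
scenario alike so that beneficial childhood BMI shifts reduce the
decrement. Person-years use the half-cycle correction
L = (l_y + l_{y+1})/2 — so a cohort whose survivor curve is flat for ten
years and then drops to zero accrues 9.5 person-years. HALYs and the
healthcare costs of the modelled diseases (costs in added life years from
unrelated conditions are excluded, following common priority-setting
practice) discount at (1 + r)^(−t), r = 0.03, with t = 0 in the first
model year.

PIFs are evaluated against the cohort's baseline-age BMI distribution for
its whole remaining lifetime rather than the cross-sectional distribution
at each attained age; with sustained effects this makes the PIF constant
per cohort and avoids conflating cohort and period distributions.

# Economics

Cost components are per-sector yearly amounts. Time costs (amounts in
person-hours) are valued at a gender-free wage rate grossed up by salary
on-costs (13% public, 14% private sector) and 17.5% leave loading;
monetary components are indexed to reference-year AUD with the health
price index (health-related) or the GDP index. The first-three-year cost
is reported undiscounted, matching the budget-impact convention of the
league table; lifetime totals discount at 3%.

ICER = net cost / HALYs gained. Dominant interventions (health gains and
net savings) have no interpretable ICER and rank by total HALYs gained;
the remainder rank by ICER against the AUD 50,000/HALY threshold. Two
corner cases the sign partition leaves open are resolved as: zero HALYs
with positive net cost → not cost-effective (infinite ICER); zero HALYs
with net savings → reported as cost-saving-health-neutral. The mid-50%
range used in portfolio summaries is defined by rank-dropping — sort,
drop ⌊n/4⌋ values from each end, report the extremes of the remainder —
because exactly this definition reproduces the published summary ranges
the package's fixtures carry (for n = 16: ranks 5–12).

The implementation-considerations ranking is lexicographic: evidence for
BMI outcomes, then evidence for nutrition/physical-activity outcomes
(high > medium > low > n/a), then equity (positive > neutral > negative),
then the count of high/positive ratings across all eight fields;
residual ties break alphabetically. The published table this reproduces
leaves its own mid-table tie order underivable from the stated rules, so
only unambiguous positions are asserted in tests.

# Uncertainty

`run_monte_carlo()` samples every parameter distribution once per
iteration and runs baseline and scenario under the same draw (common
random numbers), so incremental outputs difference out shared parameters;
intervals are 95% percentile intervals over (by default) 2000 iterations.
Default families follow standard health-economics practice — truncated
normal on effect sizes (truncated at zero on the far side so beneficial
effects stay beneficial), beta on uptake, log-normal on relative risks
(sdlog = the RR's log-scale standard error), gamma (mean 1, CV 10%) on
cost totals — and are fully configurable, as the original distribution
assignments are not documented at that granularity. Univariate
sensitivity runs one deterministic case per parameter value. Threshold
analysis bisects the raw ratio net cost/HALYs over a user bracket,
reporting a diagnostic when the willingness-to-pay crossing is not
bracketed (e.g. an intervention dominant across the whole range).

# The synthetic data: what they emulate, and what they do not

`generate_bundle()` produces an internally consistent bundle: a
22-million-person age×sex population with plausible BMI trajectories
(children tracking the growth reference plus an overweight offset; adult
medians rising to ~27.5 at 60), Gompertz mortality with a childhood
floor, age-increasing background morbidity; a nine-disease catalogue
(four cancers, type 2 diabetes, hypertensive and ischaemic heart disease,
stroke, osteoarthritis; five activity-related; two female-only) with
sigmoid incidence/fatality age curves, GBD-magnitude BMI RRs (1.02–1.10
per unit) and categorical activity RRs; an LMS growth reference; and 16
intervention templates mirroring the published study's mix (9 regulatory
/ 7 program, four child-targeted, four modelled through activity of which
two are sedentary-behaviour programs), with effect sizes set once at
literature-plausible magnitudes (e.g. −20 kJ/day population-wide for a
20% beverage tax analogue; −0.15 BMI z for community child programs;
−1 BMI unit among participants of a paid weight-loss program).

What passing tests on these data show is that the *machinery* is correct:
conversions match closed forms, PIFs match independent quadrature and the
analytic limit, the cohort engine matches an independent 50,000-agent
microsimulation, economics reproduce published league-table arithmetic
exactly. What they cannot show is calibration to any real population:
absolute HALY and cost levels depend on national epidemiology, real RR
and cost data, and real intervention effect sizes, none of which the
generator reconstructs. Real BMI distributions also drift over calendar
time and risk-factor exposures correlate across individuals — neither is
modelled (cohorts keep their baseline-age distribution; strata are
independent).

# Numerical and testing choices

* Rates → probabilities via 1 − exp(−rate) everywhere; the
  `convert_rates = FALSE` mode of `run_disease_process()` exists for
  small-rate hand checks.
* PIF integration: 2001 nodes on [10, 60]; mass-loss guard at 10⁻³ with
  expectations normalised by the numerical mass (child BMI distributions
  carry ~2×10⁻⁴ of mass below 10 kg/m², which cancels in the ratio).
* The engine's year loop and the PIF quadrature are compiled (Rcpp); the
  pure-R `run_disease_process()` is the reference implementation the
  tests compare the compiled core against, alongside the agent-level
  microsimulation oracle.
* Problem sizes in the test suite: the full synthetic study (198 strata ×
  9 diseases × 99 years × 16 interventions) runs deterministically in
  about a second; the microsimulation check uses 50,000 agents on a
  two-disease, single-cohort bundle; Monte Carlo behaviour is verified at
  2000 iterations on the toy bundle and its 2000-iteration pace on the
  full bundle is verified by running the exact workload at 125
  iterations per intervention (Monte Carlo cost is linear in the
  iteration count).

# Known limitations

Single interventions only (no joint portfolios); no lag between exposure
change and incidence change; no compensatory dietary response to activity
changes; no secular trends in incidence, mortality or BMI; no injury
pathway for transport-price interventions; sedentary behaviour acts only
through activity and BMI; deadweight losses and industry-revenue effects
enter only as optional cost components, excluded from the base case.
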
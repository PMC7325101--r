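---
title: "A cohort Markov model of the cardiovascular and diabetes burden of physical inactivity in Mexico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort Markov model of the cardiovascular and diabetes burden of physical inactivity in Mexico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdpimex)
```

## The question the model answers

Physical inactivity (PI) — accumulating less than 150 minutes of
moderate-to-vigorous activity per week, equivalently under 600
MET-minutes/week — raises the incidence of type-2 diabetes (T2D), coronary
heart disease (CHD) and stroke. Mexican national health surveys (ENSANUT)
measured a rise in PI prevalence among 35–64-year-olds from 12.1% in 2006
to 15.9% in 2012, a 31% relative increase. This package implements a
cohort state-transition (Markov) model of CVD and T2D dynamics in the
Mexican adult population, stratified by PI status, and uses it to answer
two counterfactual questions:

1. How many additional cases and deaths over a 7-year window are
   attributable to the 2006→2012 rise in PI?
2. How many cases would be averted if Mexico met the WHO targets of a 10%
   relative reduction in PI prevalence by 2025 and 15% by 2030?

## Model structure

The simulated population is held in compartments ("cells"). People
without prior CVD are classified by sex, 10-year age band (35–44 through
85–94) and a categorical risk-factor profile: smoking, systolic
blood-pressure band, HDL and LDL bands, BMI band, diabetes, and PI status.
Three submodels advance in annual cycles:

* **Demographic–epidemiological.** Annual first-event probabilities of
  T2D, CHD, stroke and non-CVD death apply to the no-CVD population.
  Event probabilities come from logistic risk functions over the
  categorical profile (intercept + age-band term + level coefficients,
  inverse-logit); population-average rates per sex and band are the
  stratum-distribution-weighted means of these.
* **Bridge.** Each incident coronary event resolves, in its first 30 days,
  into cardiac arrest, myocardial infarction or angina, each with its own
  case fatality (arrest via a survival probability); strokes carry a
  30-day case fatality. Survivors enter the disease-history compartments.
* **Disease history.** People with prior CVD live in post-CHD,
  post-stroke or post-both compartments per sex and band, with annual
  recurrence, revascularisation, CVD-death and non-CVD-death rates.
  Recurrent coronary and stroke events pass through the same bridge; a
  survivor of an event in a new territory moves to post-both.

Propagation is expected-value: compartments carry real-valued person
counts and flows are deterministic products of counts and rates. This
matches the reporting style of the original analysis — deterministic point
projections with Monte Carlo used only to propagate *input* uncertainty —
and makes every run exactly reproducible.

### Within-cycle order and conventions

Per year the engine applies, in order: (1) PI rebalancing to the
scenario's prevalence, (2) first events, non-CVD deaths and history flows
computed on start-of-year counts, (3) incident-T2D conversion of the
event-free remainder of the non-diabetic strata (the person keeps all
other factor levels and becomes diabetic with effect from the next cycle),
and (4) aging, which moves 1/10 of every band to the next band; outflow
from the 85–94 band leaves the model. The cohort is closed: no new
35-year-olds enter, matching a fixed-horizon attributable-burden
comparison. There is no half-cycle correction — targets and tallies are
annual counts, not person-years. Annual probabilities are used as rates
directly with no exponential conversion: all modelled rates are well
below 0.2/year, where the difference is second-order (`rate_to_prob()` is
provided for callers who want the exact transform). Person conservation
(counts in = counts out + deaths, to 1e-9 relative) is asserted on every
cycle, not just tested.

## How physical inactivity enters the dynamics

The effect of PI is introduced by the attributable-fraction decomposition.
Given a population-average rate $\lambda$, inactive share $p$ and relative
risk $RR$ (active vs inactive, $<1$ when activity protects),

$$\lambda_{\text{inactive}} = \frac{\lambda}{p + (1-p)\,RR},
  \qquad \lambda_{\text{active}} = RR\,\lambda_{\text{inactive}},$$

so that $p\,\lambda_{\text{inactive}} + (1-p)\,\lambda_{\text{active}} =
\lambda$ exactly. The decomposition is anchored at the *baseline*
prevalence (the 2006 survey values embedded in the bundle). The stratum
rates are then fixed characteristics of active and inactive people;
scenarios alter only the mix of the population across the two strata, so
a scenario at the baseline prevalence reproduces the calibrated
population-average rates exactly — the property calibration requires —
while a higher-PI scenario raises average rates through composition. The
functional form of the split is a design choice (the source analysis does
not state one); the attributable-fraction form was chosen precisely for
this rate-preservation property.

The relative risks are model inputs: 0.78 for incident T2D and 0.80 for
stroke (both sexes), 0.86 (men) and 0.76 (women) for CHD. Where a source
meta-analysis reports more than two activity strata, `pool_log_rr()`
collapses them by inverse-variance weighting of log RRs. PI is assumed to
act only on incident T2D, CHD and stroke — the three outcomes with
supplied RRs — not on non-CVD death.

PI rebalancing moves counts between each inactive stratum and its active
twin (the stratum identical in every other factor) keeping each pair's
total fixed, so all non-PI marginals are preserved exactly. When the
proportional scheme would drive an active twin negative (extreme targets),
the engine falls back to setting every pair's inactive share to the
target, which preserves the same marginals.

## Synthetic inputs

The original model draws on national sources — census population counts,
CONAPO projections, SINAIS vital statistics, IMSS/ISSSTE hospital
registers, ENSANUT risk-factor distributions, Framingham risk-function
coefficients — none of which are published as machine-readable inputs.
`generate_inputs()` therefore fabricates a complete, structurally valid
input bundle, deterministically per seed:

* **Population.** Counts per sex and band around the magnitudes the
  2010–2012 national figures imply (roughly 15.0, 11.0 and 7.8 million at
  35–44, 45–54 and 55–64, both sexes, with a declining tail above 65 and
  a 52/48 female/male split), with 5% lognormal jitter, all multiplied by
  `scale`.
* **Risk-factor strata.** Independent marginals per factor (Dirichlet-style
  draws around realistic priors, e.g. 20% smoking, 14% diabetes), combined
  multiplicatively. The joint distribution of the real risk factors is not
  published; independence is the minimal assumption, and the ontology is
  replaceable. The PI marginal is pinned to the 2006 survey prevalences
  (bands above 64 carry the 55–64 value).
* **Base rates.** Stratum-weighted means of synthetic logistic risk
  functions whose intercepts and age gradients put annual probabilities in
  nationally plausible ranges (CHD incidence a few per thousand per year
  at 35–44 rising roughly tenfold by 85–94, non-CVD death steeper); this
  guarantees rates increase with age and inherit seed-level jitter.
* **Bridge and history.** Event-type split about 10/45/45
  arrest/MI/angina, age-increasing case fatality, and history rates with
  total annual exit probability well below 1.

These defaults are fixed study conditions, not tuning knobs: they are
chosen once to be epidemiologically plausible and all tests run against
them. Because the absolute national input tables are unpublished, the
package's simulated absolute counts are *not* claimed to match the
published projections; what is reproduced exactly is the published tables'
arithmetic, and what is validated is the machinery — calibration,
decomposition, scenario comparison — whose structural properties do not
depend on the synthetic magnitudes. Passing tests therefore demonstrate
correctness of the method, plausible behaviour on realistic magnitudes,
and faithful arithmetic, but not numeric agreement with the original
model's unpublished inputs.

## Calibration

`calibrate()` scales four streams — CHD events, stroke events, CHD deaths,
stroke deaths — per sex and age band, by fixed-point iteration
`factor ← factor × (target/simulated)^damping`, re-simulating the base
year after every update so the population at risk reflects the current
rates. Event factors scale first-event and recurrent rates together;
death factors scale 30-day case fatalities and history CVD-death rates
(post-both deaths split evenly between streams). Iteration stops when
every stream in every stratum is within `tol` (default 1%, the original
model's stopping rule) of its target. Events are exactly linear in the
event factors and deaths linear in the death factors given events, so the
undamped iteration converges in a handful of steps; `damping < 1` is
available for oscillatory configurations. The residual metric is the
maximum over strata and streams of |simulated − target|/target.

Real 2010 SINAIS/IMSS/ISSSTE counts are not published, so calibration is
exercised through a parameter-recovery oracle:
`generate_calibration_targets()` produces targets from the model itself
under known multipliers, and the loop must recover them — which it does to
well under 1% across seeds.

## Scenarios and reporting

`constant_scenario()` holds PI at one survey year's band-specific
prevalences; `who_trajectory()` builds the WHO path: 2012 prevalences
carried unchanged to 2016 (the surveys show no evidence of change between
those years), then piecewise-linear decline in prevalence anchored at a
10% relative reduction in 2025 and 15% *total* in 2030 (the 2026–2030
phase read as inclusive; the incremental reading is available by passing
`end_reduction` accordingly). That is 9 equal decrements over 2016–2025
and 5 further over 2026–2030.

`compare_scenarios()` runs the paired simulations and reports, per
outcome, cumulative counts over the horizon for ages 35–64: T2D, CHD and
stroke incidence, total MI (first plus recurrent), CHD and stroke
mortality (bridge fatalities plus history CVD deaths attributed by
stream). Counts are kept unrounded internally; the published conventions
— counts to the nearest 100, percent difference change to one decimal,
prevalence change to the nearest integer, all half-up — are applied only
at output (`format_delta_table()`, `percent_difference_change()`,
`relative_prevalence_change()`).

The accelerometer sensitivity analysis is a pure input substitution
(`apply_accelerometer_adjustment()`): self-reported prevalences are
replaced by an adjusted table covering the same strata and years, and the
whole pipeline reruns unchanged. The Mexican adjustment equation itself is
not part of the packaged inputs; the analysis script uses a synthetic
adjusted table (uniform 1.5× inflation, capped) labelled as such.

## Monte Carlo uncertainty

`run_monte_carlo()` perturbs, per draw, every log relative risk and every
scenario band's logit prevalence by standard-normal multiples of their
standard errors (`ci_to_se()` backs SEs out of the printed 95% CIs on the
chosen scale; sampling on log/logit scales keeps RRs positive and
prevalences inside (0, 1) by construction). All draws are generated up
front from a single seed, so results are bit-identical across repeats and
independent of evaluation order. The summary reports the mean and, by
default, the standard error of the mean (draw SD / √n), mirroring the
published "mean ± SE" presentation; `se_of_mean = FALSE` reports the draw
SD. Which inputs the original analysis perturbed is not stated beyond
"1000 standard-normal draws per outcome"; perturbing the two inputs with
published CIs (RRs and prevalences) is this package's documented
interpretation, and no numeric match to the published SEs is claimed.

## Numerical choices and degenerate inputs

* Half-up rounding (`round_half_up()`) rather than IEC round-half-even,
  to match the published tables' conventions.
* Conservation and non-negativity are asserted inside the engine at 1e-9
  relative tolerance; the mixture identity of the rate decomposition holds
  to 1e-12.
* Zero rates, empty cohorts, all-inactive or all-active bands, and
  identical base/alt scenarios are all exact fixed points, covered by
  tests.
* A positive calibration target for a stream the model structurally
  cannot produce raises an infeasibility error rather than diverging;
  exceeding `max_iter` raises an error carrying the worst residual.

## Problem sizes

The packaged tests exercise compact configurations chosen for sharp
oracles and quick runs: the full 288-stratum ontology for generator and
calibration checks, a 4-stratum compact ontology for engine oracles, 1–3
age bands and horizons of 1–7 years, Monte Carlo at up to a few hundred
draws against analytic linear propagation. The analysis scripts run the
full national-scale bundle (6 bands, 288 strata per sex–band, ~3,500
compartments) with 7–15-year horizons and 200 Monte Carlo draws by
default.

## Known limitations

* Absolute projected counts depend on unpublished national input tables;
  only the structure, the published-table arithmetic and the method's
  contracts are reproducible, not the original point projections.
* Risk-factor strata other than PI and diabetes carry no rate
  differentials in the default bundle (their distributions are held
  constant, as in the source analysis); the logistic risk functions
  support them, so refined coefficient sets drop in via configuration.
* Angina survivors share the single post-CHD state; diastolic blood
  pressure is not in the default ontology (the submodel description lists
  systolic only).
* The closed cohort means WHO-horizon runs describe the aging 2016
  population, not the full future population with new entrants; entrant
  streams would be additional inputs.
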
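# cvdpimex

A cohort state-transition (Markov) simulation of coronary heart disease
(CHD), stroke and type-2-diabetes (T2D) dynamics in the Mexican adult
population (ages 35–94), stratified by physical-inactivity (PI) status.
It is aimed at epidemiologists and health-policy modellers who want to
quantify the disease burden attributable to changes in PI prevalence —
for example the observed rise among 35–64-year-old Mexicans from 12.1%
(2006) to 15.9% (2012), or the WHO targets of a 10% relative reduction in
PI by 2025 and 15% by 2030.

## The model

The population lives in compartments by sex, 10-year age band,
risk-factor profile (smoking, SBP, HDL, LDL, BMI, diabetes, PI) and
health state (no CVD, post-CHD, post-stroke, post-both). Three submodels
advance in annual cycles: first-event incidence of T2D/CHD/stroke and
non-CVD death among the CVD-free (logistic risk functions over the
categorical profile); a 30-day "bridge" resolving each incident coronary
event into cardiac arrest/MI/angina with early case fatality; and a
disease-history submodel with annual recurrence and death rates.
Propagation is expected-value (deterministic person counts), with aging
moving 1/10 of each band per year.

PI enters through the attributable-fraction decomposition of each
population-average rate λ at baseline inactive share *p* and relative
risk *RR* (active vs inactive):

    λ_inactive = λ / (p + (1 − p)·RR),   λ_active = RR · λ_inactive

so the prevalence-weighted mixture reproduces λ exactly at baseline, and
counterfactual PI trajectories act purely through the changing mix of
active and inactive people. Input RRs: T2D 0.78, stroke 0.80 (both
sexes), CHD 0.86 (men) / 0.76 (women); multi-stratum source estimates are
pooled by inverse-variance weighting of log RRs.

Further machinery: iterative proportional calibration of event/death
streams to base-year targets (all strata within 1%), WHO piecewise-linear
prevalence trajectories, paired counterfactual runs with
published-convention rounding (counts to the nearest 100, percents
half-up), an accelerometer-adjustment input substitution, and Monte Carlo
propagation of RR and prevalence uncertainty (log/logit-scale
perturbation). Because the original model's national input tables are
unpublished, a seeded synthetic-input generator emulates them; the two
published tables (survey PI prevalences; 7-year projected counts) ship as
plain-text fixtures.

## Worked example

```r
library(cvdpimex)

t2     <- load_table2_fixture()          # survey PI prevalences, as proportions
bundle <- generate_inputs(seed = 20100)  # synthetic national-scale inputs

# 7-year counterfactual: PI held at 2006 vs 2012 prevalences
s2006 <- constant_scenario(t2, 2006, start_year = 2010, horizon = 7)
s2012 <- constant_scenario(t2, 2012, start_year = 2010, horizon = 7)
delta <- compare_scenarios(bundle, s2006, s2012, 7)
format_delta_table(delta)
```

```
          outcome base_count increase percent_change
    t2d_incidence    2264600    19600            0.9
    chd_incidence    1081400     7300            0.7
 stroke_incidence     559100     4100            0.7
         total_mi     606900     3800            0.6
    chd_mortality     272800     1600            0.6
 stroke_mortality     159500     1000            0.6
```

Reading: under these synthetic inputs, the rise in PI from the 2006 to the
2012 survey levels adds ~19,600 T2D cases (+0.9% of the 2.26 million
base-case cases) over seven years among 35–64-year-olds, with smaller
relative increases for the CVD outcomes. The *absolute* counts depend on
the synthetic input magnitudes; the structure (all six outcomes increase,
relative changes under ~1%, T2D largest) is the model's substantive
output.

The table arithmetic of the published projections is reproduced exactly
from the packaged fixture:

```r
t3 <- load_table3_fixture()
percent_difference_change(t3$unadjusted_increase[1], t3$base_count[1])
#> [1] 0.8        # 10,300 extra CHD cases on a 1,267,400 base
relative_prevalence_change(0.121, 0.159)
#> [1] 31         # the published 2006 -> 2012 relative rise in PI
```

The numbered scripts under `analysis/` run the full workflow — fixtures,
synthetic inputs, calibration recovery, the 2006-vs-2012 counterfactual
(plus the accelerometer-adjusted variant), WHO 2025/2030 projections, and
Monte Carlo uncertainty — writing tables under `results/`:

```sh
Rscript analysis/01_fixtures.R
Rscript analysis/04_counterfactual.R   # etc.
```

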
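---
title: "Modelling smoking prevalence and inferring vaping-era effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smoking prevalence and inferring vaping-era effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesim)
```

## The problem

Nicotine vaping products (NVPs) entered the nicotine market while
cigarette smoking was already declining under decades of tobacco-control
policy. Transitions between vaping and smoking are too unstable and too
poorly measured to model explicitly, so `smokesim` takes the indirect
route: build a counterfactual projection of smoking prevalence that
accounts for cigarette-oriented policies but knows nothing about vaping,
calibrate it to surveys over the pre-vaping period, and read the
post-2012 gap between projection and surveys as the implied vaping
effect. That implied effect is then converted into smoking-attributable
deaths (SADs) averted by re-running the engine with the adjustment
applied and differencing the death streams.

The gap reading is deliberately *not* a causal claim: anything else that
changed after 2012 and is not in the policy set lands in the same gap.
The package models the accounting rigorously; the attribution is the
user's interpretive burden.

## Population and smoking states

The population is tracked by single year of age 0–100 (the last age is
an open band that accumulates survivors) and sex. Each year, in fixed
order, survivors age one year, net migrants arrive carrying the resident
smoking-status mix of their age/sex cell, and births enter at age 0 as
never smokers. The ordering (age/survive, migrate, births) is a
convention; all orderings agree to first order in annual rates, and
fixing one makes runs reproducible and testable.

Smoking status is never / current / former, with former smokers split
into six years-quit bins (`<1, 1–2, 3–5, 6–10, 11–15, 16+`). Transitions
follow a first-order Markov process:

- **Net initiation** through the last initiation age (male 20, female
  21 — the ages at which prevalence stops rising): the age-on-age
  prevalence increment divided by never-smoker prevalence at the
  previous age, floored at zero. Modelling initiation *net* of early
  quitting and relapse keeps the model internally consistent with
  cross-sectional prevalence profiles, which are far better measured
  than incidence.
- **Cessation** above those ages: former smokers quit less than a year
  over lagged smoking prevalence, clamped to [0, 1].
- **Relapse** by years-quit bin. National relapse rates are rarely
  published; the shipped default declines from 0.10/year (`<1` year
  quit) to 0.005/year (16+ years) and is a replaceable input to
  `transition_rates()`.

Within a simulated year the order is: policy prevalence shock, then
cessation, then initiation, then relapse, then bin ageing. Cessation and
relapse flows are computed from start-of-year stocks, and fresh quitters
enter the `<1` bin *after* bin ageing so that they spend a full year
there. Bin ageing moves the fraction `1/width` of each bin forward each
year — the standard compartmental approximation for multi-year duration
bins. Mass is conserved exactly within each age/sex cell; mortality is
applied separately.

## Policies

Each policy has effect sizes (PES) on three channels: prevalence
(one-off, in the year a policy changes level), initiation, and cessation
(both ongoing while the level holds). The registry
(`policy_registry()`) covers taxes, four smoke-free venue bans, three
marketing-restriction levels plus point-of-sale display rules, three
health-warning levels plus plain packaging, three media-campaign levels,
four cessation-treatment components plus their combined row, three
youth-access enforcement levels (age-banded), and menthol bans weighted
by covered population share.

Conventions worth stating explicitly:

- Concurrent policies combine multiplicatively, `prod(1 + PES)`, so each
  policy has an independent *relative* effect. For the cessation channel
  the signed rule is `prod(1 − PES)`; the registry stores cessation
  effects as the printed positive increases, and the engine reconciles
  the two conventions internally.
- The first-year prevalence effect of a level change is applied as the
  ratio `(1 + PES_new) / (1 + PES_old)`, which reduces to `(1 + PES)`
  for a policy introduced from nothing and correctly handles upgrades.
  Levels already in force in the first simulated year are pre-existing
  and fire no shock. Displaced smokers move to the `<1` former bin
  (above initiation ages) or back to never smokers (at initiation ages).
- Enforcement scales an effect linearly between half (score 0) and full
  (score 10): `w × (0.5 + 0.5 E/10)`. Only the endpoints are
  documented in the effect-size literature; linearity is the least
  structured interpolation.
- Taxes: the prevalence channel responds to year-over-year real price
  changes through age-banded elasticities; the initiation/cessation
  channels carry the cumulative effect versus the first tax year's real
  price and persist while the price stays above that baseline. A price
  *cut* is the one allowed "reversal".
- The four cessation-treatment components do not compound exactly to
  the published combined full-implementation row; the combined row is
  taken as authoritative (use `cessation_combined` when everything is
  in place, the components for partial implementation).

## Mortality and attributable deaths

Overall death probabilities are decomposed by smoking status each year
using relative risks: the never-smoker rate is
`D_total / Σ prev_s RR_s`, and each status rate is `RR_s` times it, so
the prevalence-weighted mean reproduces the overall rate exactly (this
identity is tested to 1e-12). SADs are excess deaths —
`N_s (D_s − D_never)` — summed over current and former smokers,
attributed in the year of death. The shipped relative-risk table
(current-smoker risk rising to ~3× by age 70, former risks decaying
toward 1 with years quit) is a documented default standing in for
study-specific tables, and is fully replaceable.

## Calibration

`calibrate()` fits multiplicative block factors (by default one per sex
and channel, bounded to [0.25, 4]) on initiation and cessation so the
modelled band prevalence tracks a survey over a pre-vaping window. The
loss is the CI-weighted squared relative error over all survey cells;
optimization is Nelder-Mead on log factors (derivative-free — the
objective is a simulation) with a soft penalty outside the bounds, and
the fit is never allowed to return factors worse than no calibration.
With noiseless targets the factors are exactly identified; under
realistic survey noise the cessation factors sit in a flatter loss
valley than initiation factors, which is visible in the test suite's
recovery tolerances.

## The indirect inference step

For each sex, band and analysis period, with `r_model` and `r_survey`
the relative reductions `(p_start − p_end)/p_start`:

```
alpha = (1 − r_model)^(1/n) − (1 − r_survey)^(1/n)
```

`alpha` is the implied per-year vaping-related relative reduction; it is
algebraically the difference of annualized reductions (tested as an
identity). Confidence bounds propagate the survey endpoint's 95% CI
through the same arithmetic; the upper reduction bound comes from the
lower prevalence bound, so bounds always bracket the point estimate.
The two survey conventions split the window differently: the monitoring
series pivots at 2017 (pre 2012–2017, post 2017–2020), the
community-health series at 2018 (pre 2012–2018, post 2018–2020), with
`n` the period length in years.

Design choices in applying `alpha`:

- A constant annualized `alpha` is used across the window (a per-year
  schedule reproduces the same endpoint by construction; constant is
  what the printed tables imply), computed per reporting band and
  applied uniformly to the single-year ages inside the band.
- The adjusted scenario re-runs the full engine with `(1 − alpha)`
  scaling inserted after the Markov step in each vaping-era year, and
  `alpha` held at zero afterwards — no post-window vaping effects are
  extrapolated. Removed smokers return to never (initiation ages) or
  the `<1` former bin (older ages), so the cell totals are unchanged.
- Negative `alpha` (survey declining slower than the counterfactual)
  pulls mass back into smoking, capped at the donor state's stock.

## The synthetic country

`synthetic_config()` defines a ~10^6-person country with a stable
pyramid under Gompertz-like mortality, a single-peaked smoking-age
profile (peak 26%/21% male/female at age 22, linear relative decline of
0.8%/year of age past the peak, adult never-smoking floor 45%),
initiation rates derived from that profile, piecewise-constant cessation
(5.5%/3.5%/5% for ages ≤34/35–64/65+), and the default relapse table.
The data-generating world distorts the analyst's rates by ×0.85 on
initiation and ×1.15 on cessation, so calibration has a real target.
An injected signal `g` makes the survey world's current smoking decline
an extra `g` per year (relative, compounding) from 2012 on.

Surveys are binomial draws per (sex, band, year) cell with Wilson 95%
intervals: n = 8000 for the open adult bands and 2000 for narrower
bands, sized to emulate the confidence-interval half-widths of the real
national series (a few tenths of a point for pooled adults early on,
over a point for sub-bands in recent years). What the generator does
*not* emulate: survey weighting and design effects, questionnaire or
mode changes, correlated nonresponse, and any pandemic-era behaviour —
so passing recovery tests demonstrates the inference arithmetic and
engine are sound, not that real surveys are unbiased.

With this design the full pipeline (generate, calibrate, project,
infer) recovers injected signals of 1–5%/year within 20% relative error
in the median across seeds, and infers no signal when none is injected;
both properties are exercised directly in the test suite. Note one
structural subtlety: because the injected signal compounds
multiplicatively on top of the counterfactual decline, the implied
`alpha` equals `g (1 − r_model)^{1/n}`, a few percent below `g` itself —
an inherent feature of the annualized-difference definition, not an
estimator bias.

## Numerical choices and degenerate inputs

- Probabilities pushed outside [0, 1] by multipliers are clamped with a
  warning; combined effects of −100% or beyond are errors.
- Initiation is undefined where never-smoking prevalence is zero at the
  previous age (error), and zero below age 10; children under 10 are
  never smokers by invariant.
- Negative populations after out-migration clamp to zero with a
  warning.
- All randomness (survey sampling, any restart) flows through explicit
  seeds; `sample_survey()` restores the caller's RNG state.
- Test problem sizes: module tests use a 2×10^5-person country to
  2030; the end-to-end recovery studies use the default 10^6 country
  with 20 seeds per signal level. A full 1999–2060 run of the default
  country takes well under a minute on a laptop-class core.

## Known limitations

- No explicit vaping states: dual use, gateway effects, and
  vaping-attributable mortality are out of scope by design; deaths
  averted are therefore an upper bound on the health gain under the
  stated assumptions.
- Policy effect sizes are literature constants, not estimated from the
  data; the inference inherits their validity over the projection
  window.
- The migrant smoking-status mix defaults to the resident distribution
  at the same age/sex; countries with strongly selected migration
  streams should supply their own decomposition.
- Former-smoker bin ageing by expected fractions slightly smears
  duration relative to exact year-by-year tracking; with six bins the
  effect on mortality decomposition is well below survey noise.
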
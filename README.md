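# smokesim

Discrete-time simulation of cigarette smoking in a national population,
with an indirect method for inferring how nicotine vaping products (NVPs)
changed smoking prevalence — and how many smoking-attributable deaths
(SADs) that implies were averted.

## Who this is for

Tobacco-control modellers and epidemiologists who want a tested, reusable
implementation of a SimSmoke-style policy simulation: cohort-component
demography, a never/current/former smoking-state Markov process, a policy
effect-size engine, smoking-attributable mortality, survey calibration,
and the counterfactual comparison machinery used to study the vaping era
in Canada-like settings.

## The model

The population evolves by single year of age (0–100, open terminal band)
and sex through births, deaths, and net migration. Smoking states follow
a first-order Markov process:

- **Net initiation** `I(a,s)` through the last initiation age (male 20,
  female 21), derived from an age profile of prevalence:
  `I(a) = max(0, (p(a) − p(a−1)) / never(a−1))`.
- **Cessation** `C(a,s)` above those ages: former-smokers-quit-<1-year
  over lagged smoking prevalence.
- **Relapse** `R(a,s,y)` by years-quit bin (`<1, 1–2, 3–5, 6–10, 11–15,
  16+`), declining with time quit.

Tobacco-control policies act as effect sizes (PES): an immediate
first-year prevalence reduction `(1+PES)` when a policy changes level,
and ongoing multipliers on initiation `(1+PES)` and cessation `(1−PES)`.
Concurrent policies combine multiplicatively. Cigarette taxes convert
real price changes through age-banded prevalence elasticities (−0.6 ages
15–20, −0.2 ages 21–34, −0.1 ages 35–64, −0.2 ages 65+).

Status-specific death rates come from decomposing overall mortality with
relative risks: `D_never = D_total / Σ prev_status · RR_status`, and SADs
are excess deaths of current and former smokers over never smokers.

The **indirect NVP inference** compares a calibrated no-NVP
counterfactual projection with survey series over 2012–2020. For each
sex and age band, the annualized survey and counterfactual relative
reductions are differenced:

```
alpha = (1 − r_model)^(1/n) − (1 − r_survey)^(1/n)
```

`alpha` is the implied per-year NVP-related relative reduction in
smoking; it is applied by moving current smokers back to never smokers
(at initiation ages) or into the `<1` year former bin (above them), and
the adjusted and counterfactual SAD streams are differenced to the
horizon.

## Worked example

```r
library(smokesim)

# the packaged Canadian comparison series (two survey conventions,
# matched no-NVP counterfactual projections, fractions)
fx <- canada_prevalence_fixture("ctums")
g  <- nvp_gain_table(fx)
subset(g, sex == "male" & band == "15+",
       select = c(period, rel_model, rel_survey, diff,
                  annual_gain, annual_gain_lo, annual_gain_hi))
#>   period rel_model rel_survey       diff annual_gain annual_gain_lo annual_gain_hi
#> 1   full    0.1913     0.3427  0.1514        0.0249         0.0114         0.0388
#> 2    pre    0.1202     0.1124 -0.0079       -0.0017        -0.0308         0.0257
#> 3   post    0.0807     0.2595  0.1787        0.0676         0.0329         0.1024
```

Reading: male smoking prevalence 15+ fell 34.3% in the survey over
2012–2020 but only 19.1% in the no-NVP counterfactual, implying an
NVP-related average annual relative gain of 2.5% (95% CI 1.1–3.9), rising
to 6.8%/year after retail vaping sales were legalized in 2018.

The synthetic pipeline end to end, with a known injected signal:

```r
cfg <- synthetic_config(seed = 7, g = 0.025)   # 2.5%/yr extra decline from 2012
p <- run_pipeline(cfg)
round(p$calibration$factors, 3)
#>   male:initiation    male:cessation female:initiation  female:cessation
#>             0.864             1.216             0.867             1.195
subset(p$report$gains, period == "full" & band == "15+",
       select = c(sex, annual_gain))
#>       sex annual_gain
#> 1    male      0.0241
#> 16 female      0.0301
p$report$sads_averted
#> [1] 1840.317
```

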
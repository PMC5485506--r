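# prostasim

Microsimulation of the benefits and harms of PSA-based prostate cancer
screening, for health-economic modelers and methodologists studying
overdiagnosis. The package simulates individual male life histories from
birth to death (120-year horizon, annual cycles): latent cancer onset and
progression over a stage × grade lattice, symptomatic presentation, PSA
screening with biopsy confirmation, stage-specific treatment (radical
prostatectomy / radiotherapy / androgen deprivation) with cure,
peri-operative mortality and long-term adverse events, optional active
surveillance of screen-detected low-risk disease, and quality-adjusted
survival. Screening strategies are contrasted against no screening under
common random numbers.

## The model in brief

Each latent state's exit time follows a mixture-cure Weibull law; the exit
hazard after *t* years in state is

    h(t) = fr · p (a/b)(t/b)^(a-1) e^-(t/b)^a / (1 - p(1 - e^-(t/b)^a))

where *p* is the fraction ever at risk of exiting, *a*/*b* are Weibull
shape/scale, and *fr* is a familial risk factor multiplying the onset and/or
progression hazards. Exits split into stage vs grade progressions with
calibrated probabilities. Overdiagnosis is measured at the population level:
the lifetime risk of diagnosis with screening minus without; overtreatment
applies the same difference to curative (RP/RT) treatment risks; the primary
benefit-harm outcome is quality-adjusted life days (QALDs) gained versus no
screening. The full account of the model, its discretization, event order,
utility accounting and the synthetic stand-ins for the three unpublished
external inputs (life table, post-diagnosis survival, age-specific
utilities) is in `vignettes/model-methods.Rmd`.

## Worked example

```r
library(prostasim)
params     <- default_parameters()                     # published base case
strategies <- strategy_catalog()[c("no screening", "55y", "55-69, 2y")]
res        <- run_cohort(params, strategies, n = 1e5, seed = 42)
res
#> <ps_comparison> 3 strategies, n = 1e+05, seed = 42 [synthetic life table / survival / utility inputs]
#>      strategy n_screens risk_dx risk_screen_dx risk_overdx overdx_frac
#>  no screening         0   10.38           0.00        0.00          NA
#>           55y         1   11.48           1.49        1.10       74.16
#>     55-69, 2y         8   20.39          13.44       10.01       74.43
#>  risk_curative risk_overtx risk_pca_death life_days_gained qald_gained
#>          10.10        0.00           2.04             0.00        0.00
#>          11.22        1.12           2.07            -2.78       -4.50
#>          20.23       10.13           1.90             2.11      -16.71
```

Reading the rows: without screening 10.4% of men are ever diagnosed and
2.0% die of prostate cancer. A single screen at 55 detects 1.5% of men; 1.1
percentage points of those diagnoses (74% of screen detections) are
overdiagnoses — cancers that would never have surfaced in the man's
lifetime — and essentially all of them are overtreated. Biennial screening
from 55 to 69 doubles the lifetime diagnosis risk, averts some cancer deaths
(1.90% vs 2.04%) and gains ~2 life days per man, but loses about 17
quality-adjusted days per man once biopsies, treatment episodes and lasting
complications are weighed in: the benefit-harm balance of average-risk
screening is negative. `default_parameters(familial = TRUE)` switches to the
elevated-familial-risk population; `strategy_catalog(surveillance = TRUE)`
defers treatment of screen-detected low-risk cancers via biennial re-biopsy.
All risks come with Monte-Carlo standard errors in the unprinted columns
(`se_*`), and `attr(res, "synthetic_inputs")` flags that the bundled
synthetic life table / survival / utility fixtures — not the original
external data — were used.

Other entry points: `run_basecase()` (full 14-strategy grid),
`sweep_cure_multiplier()`, `sweep_disutility()`,
`calibrate_familial_factor()`, `simulate_person()`, and a thin CLI at
`inst/cli/prostasim`.

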
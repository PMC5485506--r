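---
title: "Model and methods: a microsimulation of prostate cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a microsimulation of prostate cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostasim)
```

## The decision problem

PSA screening finds prostate cancer earlier, when cure is more likely, but it
also finds latent cancers that would never have surfaced clinically —
overdiagnosis — and most of those men then undergo surgery or radiotherapy
with lasting side effects — overtreatment. Whether screening helps or harms a
man therefore depends on the balance between life gained through earlier
curative treatment and quality of life lost to biopsies, treatment and its
complications. `prostasim` quantifies that balance by simulating individual
life histories from birth to death under alternative screening policies and
comparing them against no screening on a common scale, quality-adjusted life
days (QALDs).

## Natural history

Latent disease lives on a stage-by-grade lattice: stage localized, regional
or distant, and Gleason grade `G<7`, `G=7` or `G>7`. A man starts cancer-free,
may acquire a localized `G<7` tumor (onset), and the tumor may then step
through the lattice, one stage or one grade at a time, never regressing.
The holding time in each state follows a mixture-cure Weibull law: only a
fraction $p$ of a state's occupants is at risk of ever leaving it, and those
who leave do so with Weibull-distributed sojourn times. The exit hazard after
$t$ years in the state is

$$ h(t) \;=\; fr \times \frac{p\,\dfrac{a}{b}\left(\dfrac{t}{b}\right)^{a-1}
   e^{-(t/b)^a}}{1 - p\left(1 - e^{-(t/b)^a}\right)} $$

with shape $a$, scale $b$ (years) and the familial risk factor $fr$, a
hazard multiplier representing inherited predisposition that can be applied
to onset, to progression, or (base case) to both. On leaving a state, the
move is a stage progression with a state-specific split probability
(`r paste(default_parameters()$natural_history$stage_split, collapse = ", ")`
for localized `G<7`/`G=7` and regional `G<7`/`G=7`) and a grade progression
otherwise; `G>7` states can only progress in stage, distant states only in
grade. All ten exit distributions and the four splits ship as bundled,
externally calibrated defaults (`default_parameters()`; audit them with
`export_parameters_csv()`).

## From hazard to annual cycles

The simulation advances in annual cycles, so the continuous hazard must
become a per-cycle exit probability. Two conventions are implemented:

* `"pointwise"` (default): the hazard evaluated at the cycle midpoint,
  truncated at 1 — $q(t) = \min\{1, h(t + \tfrac12)\}$;
* `"discrete"`: the exact conditional probability implied by the mixture
  survivor function, $q(t) = 1 - \left(S(t{+}1)/S(t)\right)^{fr}$ with
  $S(t) = 1 - p(1 - e^{-(t/b)^a})$.

For slowly varying hazards the two are nearly identical, but several cancer
states have sub-decade Weibull scales where they diverge substantially: under
the midpoint rule the lifetime probability of leaving localized `G<7` is
about 0.23 rather than the mixture mass 0.449, and exhausted-mixture states
can exceed their nominal cure fraction. The calibrated parameter values are
only meaningful under the discretization they were calibrated with, and only
the midpoint convention reproduces the published outcome levels this
parameter set is known for (no-screening lifetime diagnosis risk near 9–10%
rather than 16%, overdiagnosis fractions near 80%, net QALD losses for
average-risk screening). The package therefore defaults to `"pointwise"` and
keeps `"discrete"` selectable via `natural_history$cycle_method` for
sensitivity analysis.

## Detection, screening and treatment

Undiagnosed cancer presents clinically with a state-specific annual
probability (from 0.006/year for localized `G<7` to 1/year for distant
`G>7`). A screening episode is a PSA test followed by biopsy when the PSA is
elevated: cancer-free men trigger a (perfectly specific) biopsy with
probability $1-\text{specificity} = 0.15$; for men with latent cancer the
calibrated whole-episode sensitivity (0.550/0.370 localized under/over age
70, 0.677/0.456 regional-or-distant) is decomposed into PSA positivity
$\text{sens}/0.90$ and biopsy sensitivity $0.90$, so a false-negative biopsy
still costs its disutility. Episodes are independent across scheduled ages
(the model carries no PSA level).

Treatment is homogeneous and stage-specific — prostatectomy (RP) for
localized, radiotherapy (RT) for regional, androgen deprivation (ADT,
palliative) for distant disease. Cure succeeds with grade-specific
probability (0.51/0.30/0.11, scaled by the `cure_multiplier` knob and
clamped to 1); RP carries 30-day mortality 0.0015; RP/RT draw erectile
dysfunction, urinary incontinence and bowel dysfunction independently with
procedure-specific risks, persisting `ae_duration` (5) years. Non-cured
treated men face an annual cancer-death probability by state at treatment,
starting the cycle after treatment (the treatment cycle itself is covered by
peri-operative mortality); this post-diagnosis survival model is pluggable
and defaults to the synthetic constant rates described below.

Active surveillance, when enabled, replaces immediate treatment for
screen-detected localized `G<7` cancers: re-biopsy every `interval` (2)
years up to age 74 detects grade progression to `G=7` or beyond with biopsy
sensitivity 0.90 and then triggers treatment at the current (possibly
progressed) state; clinical presentation remains a treatment trigger at any
time. A negative trigger biopsy simply defers to the next scheduled one;
biopsies are grade-only (no re-staging), and there is no discharge rule —
both conventions chosen because the model description specifies none.

## Event order and accounting conventions

Within a cycle: other-cause death, screening, clinical detection, diagnosis
handling (treatment or surveillance), latent progression, post-diagnosis
cancer death, utility accrual. Ties resolve in that order; a
`progression_first` switch moves latent progression ahead of the detection
steps to bound the (small) effect of this unstated convention. Deaths occur
at the start of their cycle: the death cycle is not lived, life days equal
the death age times 365.25 (days-per-year is nowhere stated), and there is
no half-cycle correction, the usual convention for annual-cycle cohort
models of this kind.

A lived cycle's utility is the age-specific baseline, replaced by the
distant-state utility 0.6 for men living with clinically detected distant
cancer (read as a state utility, not a multiplier — an interpretive choice,
flagged as such); multiplied by $1 - m(1-u_e)$ for each active treatment
complication, where $m$ is the disutility preference multiplier ($m=0$
removes, $m=2$ doubles impairment); and multiplied by one-time relative
weights in the cycle of the event: 0.994 per biopsy, 0.753 for RP, 0.772
for RT, 0.7 in the final cycle before cancer death. Same-cycle weights
compose multiplicatively. Latent (undiagnosed) cancer carries full baseline
utility. By construction QALDs never exceed life days.

## Common random numbers

Every random quantity is drawn from a substream keyed by purpose and cycle,
derived from the base seed by an integer hash. Strategy-independent draws —
the latent trajectory, other-cause death age, clinical presentation age, and
the person-level uniforms inverted for cure, surgical death, adverse events
and post-diagnosis survival — are sampled once per cohort context and shared
by every strategy evaluated on it. Screening draws are keyed by age, so two
strategies that both screen at 57 see identical episode outcomes. This makes
contrasts exact where they should be (zero-sensitivity screening equals no
screening bitwise; diagnosis is monotone person-by-person in nested
screening-age sets) and shrinks the Monte-Carlo error of differences such as
QALDs gained by orders of magnitude. Runs are bitwise reproducible from
`(n, seed)`.

## Synthetic stand-ins for external inputs

Three inputs of the original analysis are not printed anywhere and ship as
clearly labeled synthetic fixtures; swapping in real tables changes numbers,
not code paths, and every result table carries a `synthetic_inputs` flag.

* **Life table** (`synthetic_life_table()`): Gompertz–Makeham
  $q(x) = 1-e^{-(A+Bc^x)}$ with $A=4\times10^{-4}$, $B=3\times10^{-5}$,
  $c=1.10$, giving survival-to-55 of 0.925 and life expectancy 78.3 y —
  the ballpark of a recent Western European male period table, not official
  data. Substitute a real table via `read_life_table()` for exact
  reproduction.
* **Post-diagnosis survival** (`synthetic_postdx_rates()`): constant annual
  cancer-death probabilities by state at treatment, ordered in stage and
  grade (localized 0.005/0.015/0.04, regional 0.02/0.05/0.10, distant
  0.20/0.25/0.30). Registry-based conditional survival would fall with time
  since diagnosis; a constant rate instead imposes lifelong cancer mortality
  on non-cured men with indolent screen-detected disease, which depresses
  the simulated life-day gains of sparse screening relative to the published
  analysis. This is the main reason the familial population's QALD balance
  only turns positive for intensive interval screening here.
* **Baseline utilities** (`synthetic_utility_table()`): piecewise-linear
  1.00 at ages ≤ 35 to 0.78 at ages ≥ 90, matching only the published range.

Because of these stand-ins, passing tests demonstrate that the mechanics and
the published *relative* structure (overdiagnosis fractions, testing loads,
harm counts, directions of effect) are reproduced; absolute mortality- and
life-expectancy-level outcomes are fixture-dependent and are checked only
directionally.

## Experiments and problem sizes

`run_basecase()` evaluates the 14-strategy grid (no screening; one-time at
55/59/64/69; 4-, 2- and 1-yearly screening over 55–59, 55–64, 55–69) for an
average-risk or familial population, with or without surveillance.
`sweep_cure_multiplier()` scales cure rates up to +80%;
`sweep_disutility()` varies $m$ over 0–2 for screening candidates aged
55/60/65 (schedules shifted, outcomes conditioned on being alive and
undiagnosed at the index age) and maps the QALD-optimal strategy;
`calibrate_familial_factor()` bisects $fr$ until the no-screening lifetime
diagnosis risk reaches a target multiple of the average-risk value — with a
shared seed the risk is monotone in $fr$, so bisection is stable down to
Monte-Carlo resolution.

The package's own test suite runs cohorts of $10^4$–$2\times10^5$ men and
the bundled acceptance script $5\times10^5$ per arm with $2\times10^5$ per
calibration step; these sizes put Monte-Carlo standard errors of lifetime
risks below ~0.1 percentage points while keeping a full run in minutes on
one core. Larger cohorts only tighten the standard errors reported alongside
every aggregate.

## Known limitations

* No PSA-level growth model, no re-staging at surveillance biopsies, no
  salvage treatment lines, no ADT side-effect model, no discounting (by
  design — the analysis takes the individual decision perspective).
* Disease state is frozen at treatment: post-treatment progression to
  symptomatic distant disease is not represented except through the
  post-diagnosis survival model, so the distant-state utility applies only
  to men *diagnosed* at distant stage.
* The constant-rate post-diagnosis fixture overstates long-run cancer
  mortality of non-cured indolent disease (see above).
* The within-cycle event order and the hazard discretization of the original
  implementation are not documented; both are configurable here, and the
  defaults are the combination that reproduces the published outcome levels.
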
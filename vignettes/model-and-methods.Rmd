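---
title: "A hybrid decision-tree Markov microsimulation for diabetes screening and lifestyle-intervention economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmprevent)
```

## The question the model answers

In settings where diabetes is mostly detected late, a one-off population
screen for undiagnosed diabetes and impaired glucose tolerance (IGT),
followed by a six-year lifestyle intervention in the people found to have
IGT, competes for scarce health resources against doing nothing.
`dmprevent` simulates five strategies over a 40-year horizon — screening
with a diet intervention, with an exercise intervention, with both
("duo"), screening alone, and an unscreened control — and compares them on
remaining survival years, quality-adjusted life years (QALYs), discounted
societal costs, cost savings, and the time gained before diabetes onset
and before diabetes complications, at initiation ages 25, 40 and 60.

## Model structure

The model is a hybrid of a decision tree and an annual-cycle Markov
microsimulation.

**Decision tree (baseline assignment).** Each simulated adult is assigned
a latent glucose state from the screening cascade: a fraction
$1 - 0.96 = 0.04$ is 2-h plasma-glucose positive; $0.305$ of the positives
have a positive oral glucose tolerance test (OGTT); of these, $0.478$ have
IGT and the remainder undiagnosed diabetes.  Screen-negatives are treated
as normal glucose tolerance.  The latent distribution is identical in all
arms — arms differ only in whether a subject attends screening (probability
`compliance`), whether IGT is detected (`detection_level`), whether a
detected IGT subject receives the lifestyle intervention (diet, exercise
and duo arms only), and the screening fee incurred by attendees.
Unattended and undetected subjects follow the control arm's fate while
remaining in their arm's cohort.

**Markov core.** Eight health states: normal glucose tolerance, IGT, onset
of diabetes, four mutually exclusive complication states (cardiovascular
disease, retinopathy, nephropathy, overt neuropathy) and death.  The IGT
state is expanded into six *tunnel* states so that residence time is
observable — the six tunnel years are the intervention window — plus a
post-tunnel IGT state.  Transitions per cycle:

* normal → IGT at 0.0128/year; IGT → normal at 0.116/year (derived from a
  3-year cumulative reversion of 0.3084 via
  $1-(1-0.3084)^{1/3}$, see `annual_rate_from_cumulative()`);
* IGT → onset of diabetes at the arm- and age-specific annual rate
  (e.g. control 0.0644/0.1670/0.5778 at ages 25/40/60; diet
  0.0290/0.0754/0.2320).  Age-25 and age-60 rates derive from the age-40
  anchor by the incidence ratio 1:2.6:8 (`scale_rate_by_age_ratio()`);
  printed values are stored verbatim where a table cell deviates from the
  exact ratio in the fourth decimal;
* onset of diabetes → each complication at its annual incidence; CVD and
  nephropathy add disease-specific mortality on top of the life-table
  hazard; retinopathy and neuropathy are not independently fatal;
* all living states are exposed to life-table background mortality first,
  and disease transitions apply conditionally on surviving the cycle.

Intervention recipients use their arm's IGT→diabetes rate while in the
tunnel during the first six cycles and the arm's complication rates for
life; after the tunnel (and for any later re-entry into IGT) the control
progression rate applies (`settings$post_tunnel_rate`, switchable to
`"last_intervention"`).  Incident IGT arising after baseline is never
intervened — screening is one-off.

**Screening alone.** The transition contract gives non-intervened subjects
control-arm dynamics, so by default the screening-alone arm differs from
control only through the screening fee and diagnosis flags.  Its
separately tabulated progression column (0.0400/0.104/0.3600), which would
attribute a progression benefit to diagnosis alone, can be applied to
diagnosed IGT subjects with
`settings$screen_alone_uses_column_rates = TRUE`.  The default keeps the
conservative reading: it is the only one under which screening alone gains
essentially zero time before onset, which is what the reported results
show for that arm.

## Economic valuation

Costs are societal, in US dollars at a fixed CHY 7.6948 per USD.  Annual
state costs: onset of diabetes 897, CVD 2078, nephropathy 1089, neuropathy
1324, retinopathy 888.  The lifestyle intervention costs 362 (diet or
exercise) or 371 (duo) per year and is charged for each tunnel year an
intervened subject completes, valued at the end of that year.  Screening
costs $3 per attendee, charged in full at cycle 0 (a point event, so it is
neither discounted nor half-cycle weighted).

Utilities are tabulated per initiation age (normal 1, IGT 0.95, death 0;
disease states anchored at age 40 and adjusted by −0.0003 utility per year
of age, plus a 0.084 decrement for the third coexisting condition that
applies to complication states in the age-60 models — e.g. diabetes with
CVD at 60: $0.674 - 0.006 - 0.084 = 0.584$, see `adjust_utility()`).

Costs and QALYs are discounted at 3%/year and half-cycle corrected
(trapezoidal weights: 0.5 at cycle 0 and at the horizon).  Survival years
are undiscounted half-cycle-weighted years alive, so a subject dying in
the first cycle contributes half a year.

## Outcome definitions

* **Remaining survival years / QALYs** are averaged over the diabetes/IGT
  subgroup: subjects with baseline IGT, baseline diabetes, or (default
  `settings$eligibility = "baseline_plus_incident"`) incident diabetes
  within the horizon.  Intervals are subject-level 2.5–97.5 percentiles
  (`settings$range_type`, switchable to min–max).
* **Costs** are averaged both over all simulated subjects and over the
  subgroup; `settings$cost_population` (default `"subgroup"`) selects
  which is reported and drives savings.
* **Extra time before onset / complications** is computed among
  baseline-IGT subjects as the between-arm difference in event-free years:
  time to first entry into the event state, cut at death and at the
  horizon.  Cutting at death matters: without it, an intervened
  60-year-old who dies diabetes-free would be scored as 40 event-free
  years, and "extra time" would *grow* with initiation age.
* **Savings** and **increment QALYs** are per-strategy differences versus
  the control arm run on the same random numbers.

## Random numbers and variance reduction

One master seed drives everything.  Baseline assignment consumes one
uniform per subject through an inverse-CDF over a canonical branch
ordering whose latent-state blocks coincide across arms, so a subject has
the same latent state, and the same screening-attendance decision, in
every arm and in every sensitivity scenario (common random numbers).  The
Markov engine consumes two uniforms per subject-cycle: one against the
life-table death probability — shared across arms, so background death
times are identical everywhere — and one against the survival-conditional
transition row, with the fixed state ordering (normal first, then the IGT
states, onset, complications, death).  With that ordering, a treated
subject and their control twin revert to normal on exactly the same draws,
and divergences occur precisely on postponed-onset events.

Even so, comparative outcomes are driven by the roughly
$20{,}000 \times 0.04 \times 0.305 \times 0.478 \approx 117$ intervened
subjects per arm, so arm-versus-control cost differences retain a
Monte-Carlo standard error of a few tens of dollars per subgroup subject
at the default cohort size.  Properties that hold in expectation — for
example that savings shrink monotonically as screening compliance falls —
can invert by a few dollars between adjacent compliance levels in a single
run.  The test suite therefore pins such orderings at fixed seeds and
states the chains it observed, and exercise and duo arms (whose rates
differ by 0.0002) can produce identical trajectories in a given run.

## Synthetic inputs

No suitable public life table ships with the package, so background
mortality comes from a Gompertz–Makeham fixture,
$q_x = 1 - \exp(-(a + b c^{x}))$ with $a = 5\times10^{-4}$,
$b = 3\times10^{-5}$, $c = 1.094$ over ages 25–100, frozen at
`inst/extdata/life_table_synthetic.tsv` and regenerable with
`generate_life_table()`.  It yields a horizon-capped expected survival of
38.6 years for a healthy 25-year-old and residual life expectancies of
about 57/43/25 years at 25/40/60 — a deliberately smooth, slightly
optimistic schedule; it is *not* a national table, and absolute
survival-dependent outputs (remaining years, and through them costs and
QALYs) inherit this calibration.  The parameters were fixed from the
life-expectancy considerations above, not adjusted against any output.

The cohort generator (`generate_test_cohort()`) produces everything the
analysis assumes statistically: the screening-yield multinomial,
intervention flags and reproducible per-arm cohorts.  What it does not
emulate about real populations: age structure within a cohort (all
subjects share the initiation age), secular trends in incidence, repeat
screening, behavioural risk factors, and any correlation between screening
attendance and health status.  Green tests therefore certify the model
mechanics and its internal conventions, not external validity.

## Numerical and design choices

* Event ordering within a cycle: background death first, then disease
  transitions conditional on survival; complication states are absorbing
  except for death.
* Transition rows are validated to sum to 1 (±1e−12) for every strategy,
  age, cycle-regime and the extreme attained ages at start-up
  (`validate_transitions()`).
* Negative residual stay-probabilities (possible when sensitivity
  multipliers push IGT exit rates past 1) raise an error naming the state;
  probability and utility multipliers clamp to [0, 1] with a warning.
* Reported parameter values round half away from zero at the published
  precision (`round_half_up()`); internal computation is unrounded.
* The Wilcoxon rank-sum test uses exact enumeration (subset-sum dynamic
  programme over rank sums) for untied samples up to 20 per arm and a
  tie-corrected, continuity-corrected normal approximation otherwise.
* Problem sizes in the test suite: full acceptance-style runs use the
  study size of 20,000 subjects per arm; property checks that do not need
  the full size use 1,200–20,000 subjects, and the 1/√n error-scaling
  check uses 2,500/10,000/40,000 with eight replicate seeds.

## Known limitations

* Sustained post-tunnel benefit is limited to the averted or postponed
  onsets accrued during the six intervention years; if the true effect
  persists, savings are underestimated (the `post_tunnel_rate` switch
  explores the opposite extreme).
* Undiagnosed diabetes in the control arm accrues full treatment costs
  from entry into the onset state; no separate undiagnosed-cost schedule
  is modelled.
* With the screening cascade's ~0.6% baseline IGT yield, subgroup-averaged
  comparative outcomes are small per subject; published cohort-style
  analyses that condition on the screened-positive branch produce
  magnitudes orders larger, and users comparing against such figures
  should average within the baseline-positive subgroup
  (`settings$eligibility = "baseline_only"`) and interpret accordingly.
* One cohort per initiation age; no mixed-age population, no repeat
  screening, no future (unrelated) medical costs.

## A minimal run

```{r, eval = FALSE}
run <- run_model(n = 20000, seed = 1)
run$summary
compare_arms(run, outcomes = "qalys")
sens <- run_sensitivity(n = 5000, seed = 1)
pivot_savings(sens)
```
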
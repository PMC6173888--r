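---
title: "Smartwatch activity feedback and trial feasibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartwatch activity feedback and trial feasibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`swaft` implements the computational core of a smartwatch activity-feedback
intervention for inpatient stroke rehabilitation, together with the
feasibility analytics of the pilot trials that evaluate such interventions.
This vignette documents the models, the tunable parameters, the numerical
conventions, and what the synthetic cohort does and does not emulate.

```{r setup, message = FALSE}
library(swaft)
library(dplyr)
```

## The intervention model

The watch monitors a fixed daytime window, 08:00–17:00, divided into five
consecutive periods: four of 2 h and one final 1-h period (the short period
matches the remaining battery). `build_epochs()` instantiates these
half-open windows for any date; every daytime instant belongs to exactly
one period.

```{r}
build_epochs(as.Date("2015-11-16"))
```

### Activity score

The per-epoch **activity score (AS)** summarises overall body movement from
the tri-axial accelerometer. The watch firmware on which this design is
based does not publish its exact formula, so the package defines a
documented, configurable stand-in with the same *relative* semantics
(day-to-day comparison, not calibrated energy expenditure):

$$
\mathrm{AS} = \sum_i \max\big(\,\lvert\,\lVert a_i \rVert - 1\,\rvert - d,\; 0\big)\,\Delta t
$$

where $\lVert a_i \rVert$ is the vector magnitude of sample $i$ in g,
the subtraction of 1 g removes gravity's magnitude, $d$ is a dead-band
(default 0.05 g, `scoring_config()`) suppressing sensor noise, and
$\Delta t$ is the sampling interval (estimated as the median timestamp
difference). The score is non-negative, zero for a stationary wrist,
additive over partitions of a window, and invariant to the *orientation*
of gravity (rotating all samples leaves vector magnitudes unchanged). It
deliberately rewards both short intense bursts and sustained low-intensity
movement equally per unit of magnitude deviation. Absolute AS values are
arbitrary units: analyses built on them (exceedance, deltas, summaries)
only ever compare a patient with themselves or rank days.

### Wear detection

Whether the watch was actually on the wrist is inferred from movement
alone: the window is tiled into 60-s sub-windows, a sub-window is *active*
when the variance of the vector magnitude is at least
$10^{-4}\,\mathrm{g}^2$, and the watch counts as worn when at least 25% of
sub-windows are active (`wear_config()`; all thresholds inclusive). Tiling
(step = width) rather than overlapped sliding makes `worn_fraction` an
exact partition count that a brute-force enumeration can verify.
Movement-based wear detection is conservative by construction — a patient
lying still reads as not wearing the watch — which matches how such
devices under-estimate wear in practice.

### Goals and the four-bar display

Each day after the first, the goal for a period is **1.05 × the AS of the
same period on the preceding watch weekday**; Friday's scores set Monday's
goals (`comparable_previous_day()`, `set_goal()`). The first intervention
day is a per-period baseline and shows no feedback in any arm. The display
(`bar_state()`) has four levels with thresholds at 1/3, 2/3 and the full
goal, inclusive; a zero goal counts as met (level 4), which keeps the
display well-defined for a patient whose comparable epoch recorded no
movement. Control-mode output carries the period (clock) icon only and
never a bar level.

Where the comparable epoch is missing (watch not worn, file lost,
weekend), the goal falls back in order to: the most recent recorded
same-period score, the baseline score, then a configured default
(`goal_config()`); the provenance is flagged in the output. Weekend
activity, even when recorded, never feeds Monday goals — Friday does.
Goals may ratchet *down* after a low-activity day because the rule ties
the goal to the previous day, not to a running maximum; that is faithful
to the stated rule. Period 5 carries goals and feedback symmetrically with
periods 1–4, but all analytics exclude it (below).

## Trial bookkeeping

Eligibility (`screen_eligibility()`) is a pure conjunction: age 40–75,
stroke onset under 4 months (operationalised as < 122 days, configurable),
first rehabilitation admission, able to walk 10 m unaided pre-stroke,
sufficient cognition and vision, two-stage command, capacity to consent.
Failing *only* the two-stage command defers the decision to a 3-day
recheck. An explicit `override` flag admits demographic protocol
deviations while recording them, so deviation reports can be generated.

Randomisation (`randomise()`) defaults to simple 1:1 draws from a
seed-fixed concealed sequence consumed in registration order — the
allocation of patient *k* never depends on later data, and regenerating a
longer sequence from the same seed preserves every earlier assignment.
Permuted blocks are available where exact balance is wanted. Observation-
phase patients bypass randomisation. Force-registering an ineligible
candidate creates a record flagged invalid, reproducing the "accidental
registration" failure mode that feasibility analyses must be able to
exclude post hoc.

## Feasibility analytics

All analytics work on the daily total AS over **periods 1–4 only**
(08:00–16:00); period 5's duration varies with battery life, so it is
excluded (`daily_total()`).

- **Flow rates** (`flow_rates()`): recruitment = recruited/admitted;
  retention at discharge and follow-up = completers/valid patients;
  follow-up among discharged = follow-up completers/discharge completers.
  Integer percent, matching how such rates are reported.
- **Exceedance** (`exceedance()`, `exceedance_table()`): a post-baseline
  day exceeds baseline when its daily total is *strictly* greater than the
  day-1 total; the baseline day can therefore never count itself. Rates are
  reported against two denominators: *expected* days (weekdays spanned by
  each patient's intervention, from first watch day to discharge or, when
  discharge is unrecorded, the last day with data) and *actual* days (days
  with recorded data — weekend recording can push actual above expected).
- **Adherence** (`adherence_table()`): every recorded day is classified by
  how many of periods 1–4 were worn; each day lands in exactly one of the
  {4, 3, 2, 1, 0} categories. Because deployed reports have mixed the two
  percentage bases row by row, both are always computed
  (`*_pct_weekday`, `*_pct_recorded`); only the weekday-based ≥ 1-period
  ratio can exceed 100%.
- **Completion** (`completion_table()`): five performance-based and five
  self-report measures at baseline and discharge, three telephone measures
  at 3 months (`measure_sets()`); per group×timepoint×set, the number of
  patients completing everything plus the min–max per-measure completion
  percentage.
- **Summaries and deltas** (`activity_summary()`, `delta_metrics()`):
  medians and quartiles of daily totals at selected weekday indices (day 1
  = first watch day; weekends excluded from indexing), and per-period
  differences from baseline and from the comparable previous day, with
  missing days propagating as `NA`, never as zero.

Quantiles use the inclusive linear-interpolation rule (R type 7), stated
here because summary tables in the field rarely say which rule they used.
Percentages are printed to 1 decimal in adherence/exceedance tables and as
integers in flow rates, matching reporting precision. No between-arm
inferential statistics are provided: a feasibility cohort of this size is
underpowered by design and testing would be misleading.

## The synthetic cohort

`simulate_cohort()` generates a full synthetic trial so every operation is
testable without device data. Its defaults are the study conditions of a
single-site inpatient deployment and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| recruitment | eligibility 0.20 × consent 0.55 | ≈ 11% of admissions recruited |
| phase mix | 40% observation / 60% RCT | 20/30 split at a 50-patient cohort |
| length of stay | lognormal, mean 17.5 d | 2–3 week inpatient stay |
| activity level | lognormal, log-mean log(120), log-sd 0.6 | heavy inter-patient variability; daily totals spanning the observed scale of medians |
| epoch noise | lognormal, log-sd 0.3 | within-patient day-to-day variation |
| wear probability | 0.85 per period | RCT-phase adherence levels |
| recording | 0.97 weekday, 0.30 weekend | few lost weekday files; optional weekend wear |
| dropout before discharge assessment | 0.22 | reproduces the 78%/48% retention pattern |
| follow-up contact | 0.62 of discharge completers | telephone follow-up reach |
| feedback effect | 0.10 multiplicative uplift after day 1 | modest behavioural effect |

The intervention runs Monday–Friday for up to 15 watch days within 21
elapsed days, or until discharge if sooner. Activity for patient $i$ on
day $d$, period $p$ is
$L_i \cdot \tau^{d-1} \cdot (1 + e \cdot \mathbb{1}[\text{feedback}, d>1])
\cdot \varepsilon_{idp}$ with lognormal level $L_i$ and noise
$\varepsilon$; non-worn periods record zero. Dropout is
missing-at-random given arm and day. All randomness is fixed by the seed;
identical configurations give byte-identical output.

`simulate_accel_trace()` closes the loop at the raw-signal level: it
builds a uniformly sampled trace whose computed AS equals a requested
level (the construction is exact up to floating point — alternating
high/rest magnitudes around 1 g whose post-dead-band contributions sum to
the target), with seeded random 3-D movement directions and pure-gravity
non-worn stretches. Worn stretches always carry super-threshold variance,
so wear detection sees them.

What the simulator does **not** emulate: duplicate/mislabelled files arise
only when tests construct them explicitly; activity has no circadian or
therapy-schedule structure within a period; dropout is not informative
(real dropout may correlate with severity); and no clinical outcome
trajectories are generated beyond completion flags. Passing tests
therefore demonstrate the correctness of the bookkeeping and the
statistical machinery under a plausible data-generating process, not the
clinical realism of that process.

## Numerical choices and degenerate inputs

- Windows are half-open `[start, end)`, local clock, no daylight-saving
  handling (single-site, single-timezone deployments).
- Thresholds are inclusive (≥) everywhere: bar levels, wear variance,
  worn fraction, screening ages.
- An empty trace scores 0 with a `no_data` flag and reads as not worn; a
  single sample carries no sampling interval and scores 0; non-monotone or
  non-finite timestamps are rejected outright.
- A zero goal maps to bar level 4; zero denominators in any rate yield 0
  rather than an error.
- Days where only period 5 was recorded are missing days for analytics,
  not zero-activity days.
- Battery truncation of period 5 is modelled as missing data, not as a
  variable-length period.

## Problem sizes used in validation

The packaged test-suite and the acceptance script validate against:
printed summary-count tables of a 50-patient deployment (exact arithmetic
checks); 100 randomised small fixtures compared against independent
brute-force oracles (traces of a few hundred samples; 5-day cohorts);
simulated cohorts of n = 1000 for retention-recovery checks (3 standard
errors) and n = 200 per arm-contrast check. These sizes give stable Monte
Carlo behaviour while keeping a full run inexpensive.

## Known limitations

- The AS is a stand-in with matching relative semantics; absolute AS
  magnitudes from deployed watches are not reproducible and are never
  asserted.
- Movement-based wear detection cannot distinguish a still wrist from an
  unworn watch; worn time is under-estimated.
- The weekday-indexing convention assumes interventions start on a
  weekday, which registration logic guarantees but imported registries
  should respect.
- The adherence table's dual percentage bases exist precisely because
  deployed reports have been internally inconsistent; consumers must pick
  a base explicitly rather than trust a single printed column.
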
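---
title: "Methods: models, rules, and simulation design in promptsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules, and simulation design in promptsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptsleep)
```

promptsleep implements the computational machinery of a four-week
smartphone-delivered brief behavioral therapy for insomnia and of the
two-arm randomized trial that evaluates it. This vignette records the
models, the parameter choices that matter, and the places where the
design was genuinely open — and what the simulation-based tests do and do
not demonstrate.

## Sleep-diary arithmetic

Diaries record clock times only (`"HH:MM"`), never dates for the night's
endpoints, so all intervals live on the 24-hour circle. We represent a
clock time as integer minutes since midnight in `[0, 1440)` and resolve
the bed interval with a single wrap rule: if the final arising time
(final awakening + bed-out latency) falls at or before the bedtime on
the clock face, the interval crosses midnight and 1440 minutes are
added. A zero-length interval is rejected outright because sleep
efficiency divides by it. Two invariants pin the arithmetic down: time
in bed is invariant under shifting both clocks by the same offset, and
`TIB − SOL − WASO − BOL = TST` holds exactly in integer minutes for
every valid entry.

Validation is strict: a diary row with any missing required item is
invalid rather than imputed to zero, since a silently imputed latency
would bias sleep efficiency upward. Entries whose latencies exceed the
bed interval (negative sleep) or that report awakening minutes with zero
awakenings are rejected at construction. Naps and daytime-sleepiness
times are stored and exposed to the prompt engine as state, but never
enter TIB/TST/SE — the program's formulas are defined on the nocturnal
interval only.

Sleep efficiency is kept at full precision internally and rounded to one
decimal place only at presentation.

## Weekly titration

Sleep-restriction therapy runs in weeks 2–4. The recommended bedtime is
the desired wake time minus (last week's mean total sleep time + 30
minutes); the weekly adjustment is driven by the diary-derived mean
sleep efficiency: above 90% the prescribed window grows 15 minutes, from
85% to 90% (both endpoints included, matching the `>90 / 85–90 / <85`
partition) it holds, below 85% it shrinks 15 minutes. Choices the rule
itself does not fix:

- **Anchor.** The adjustment moves the *bedtime*; the wake time is the
  participant's anchor and the more behaviorally stable endpoint. The
  schedule records both the recommended and the set bedtime (simulation
  sets them equal).
- **Safety bounds.** The prescribed window is clamped to
  [300, 600] minutes. Five hours is the conventional floor of
  sleep-restriction protocols (restricting further trades adherence for
  little consolidation); ten hours rejects degenerate inputs.
- **Adherence.** A weekly mean over fewer than 3 recorded days is
  considered unreliable; the week is flagged non-adherent and the
  previous schedule is carried forward unchanged. Three days balances
  robustness of the mean against discarding usable weeks.
- **SE source.** The titration consumes the diary-derived weekly mean
  SE, not the schedule-implied one: the program reacts to what the
  participant recorded, not to what was prescribed.

Monotonicity (low SE never extends the window, high SE never shrinks
it, steps are exactly 0 or ±15 minutes, bounds never violated) is
enforced by property tests over randomized weekly histories.

## Prompt engine

Messages carry a category (diary feedback, praise, hygiene, stimulus
control, restriction), a topic, one or more of four daily slots, a
priority, and a declarative firing condition. Week gating follows the
program: hygiene, diary feedback, and praise run weeks 1–4; stimulus
control and restriction start in week 2.

The rule language is deliberately tiny — field/comparator/value leaves
with `all`/`any`/`not` combinators, serialized as JSON with the catalog —
so catalogs are data, not code, and predicates are total and
side-effect-free (a comparison on a missing field is false, never an
error). Remaining free parameters, fixed once:

- **Daily cap 4** (one message per slot), minimum one when anything is
  eligible; "several times a day" is otherwise unquantified.
- **Slot anchors**: after waking = last recorded arising time + 30 min
  (07:30 before any diary exists); around noon = 12:00; evening =
  18:00; before bedtime = set bedtime − 60 min (22:30 without a
  schedule). Anchors snap to the nearest edge of a declared
  receptive-time window, by circular distance.
- **Cool-down 7 days** between repeats of the same message, so a
  month-long program cycles content.
- **Praise trigger**: 3 consecutive diary days ("consistent" entry
  needs a number; 3 matches the adherence threshold above).
- **Tie-break**: priority, then least-recently-sent (never-sent first),
  then lowest message id — so a replayed 28-day schedule is
  bit-identical across runs, which the tests assert.

The shipped catalog (~40 messages) is a seed demonstrating the schema
across all five categories and the hygiene topics (light, rhythm,
caffeine, alcohol, smoking, exercise, napping, bathing, diet,
temperature, noise, emotional distress); production use would load a
full catalog through the same reader. The rule schema can reference sex
and age; the seed catalog does not, since no published rule uses them.

## Instruments

Scores are plain item sums with inclusive cutoffs (ISI ≥ 8 insomniac;
strata < 8, 8–14, ≥ 15; PHQ-9 ≥ 10 excluded; BMI ≥ 25 obese). No
prorating: any missing item renders a response missing. The Chalder
scale uses Likert 0–3 scoring only (global 0–33 = physical 0–21 +
psychological 0–12); bimodal scoring is out of scope.

Two conventions worth flagging. First, the HPQ short form's absolute
presenteeism is defined as 10 × the B11 self-rating (actual performance
over the past 4 weeks); source descriptions sometimes attach the
1–2-year recall wording to that formula, but B11 is the standard HPQ
item and is what we use. Second, the self-harm exclusion ("more than
half of the days") corresponds to PHQ-9 item-9 response codes ≥ 2 under
the standard anchors (0 not at all, 1 several days, 2 more than half
the days, 3 nearly every day).

## Trial machinery

Randomization pre-generates, per sex × ISI stratum, a seeded sequence of
random permutations of the AABB block (size 4, ratio 1:1) and assigns by
arrival order. This makes the allocation a pure function of roster order
and seed, balanced after every complete block, and invariant to
relabeling participants.

The sample-size routine is the two-sample normal-approximation closed
form `n = ⌈2 (z₁₋α/₂ + z_power)² σ² / δ²⌉`; with δ = 1.3, σ = 2.3,
α = .05, power .80 it yields 50 per group, and the t-corrected iterative
version would not (it gives 51). Attrition inflation is multiplicative,
`⌈n (1 + rate)⌉`, the convention under which 100 analyzable participants
and 20% attrition give an enrollment target of 120.

Baseline contingency tests use the plain Pearson statistic with **no
continuity correction at any table size**: the published ISI-8 subgroup
statistics (6.81 for the 2×3 alcohol-use table, 3.90 and 5.85 for the
2×2 smoking and alcohol-as-sleep-aid tables) reproduce only under that
form. One known discrepancy: the total-population alcohol-as-sleep-aid
table (1/59 vs 6/50) yields 4.18 by any standard form, not the printed
4.22; the table ships as the fixture `table1-total-sleep-aid` but no
test asserts the printed value.

Change-score comparisons use Welch's t test (no equal-variance
assumption). Two degenerate cases are defined rather than erroring:
identical constant samples give difference 0 with p = 1; a pure constant
shift gives the shift with p = 0.

## Longitudinal model

The primary analysis is a linear mixed model with a random intercept per
participant and fixed effects for week, arm, and week × arm; the
interaction is the primary effect. Open choices, and how they were
fixed:

- **Time coding**: continuous weeks 0–4 with a linear trend, the
  smallest model in which "difference in temporal trends" is one
  coefficient; a categorical-time variant is available via
  `time_coding = "categorical"` as a sensitivity analysis.
- **Baseline**: modeled as the week-0 response (five time points), not
  as a covariate.
- **Estimation**: REML, with Satterthwaite degrees of freedom for the
  Wald tests (`p_method = "wald"` gives the normal approximation, used
  inside large simulation loops where the two are indistinguishable at
  ~570 observations).

With noise-free balanced data the fixed effects are recovered to
numerical precision, and dropping a single participant-week changes only
that participant's contribution — there is no imputation pathway.

## Synthetic cohort

The simulator generates exactly the structure the analysis model
assumes, so the model is correctly specified by default:

`isi_iw = b_i + w · (β_ctl + [i ∈ SPA] · β_extra) + ε_iw`,

with `b_i ~ N(9.2, 3.0²)`, `ε ~ N(0, 2.5²)`, then rounded and truncated
to integers in [0, 28]. Defaults are calibrated to a plausible worker
cohort: β_ctl = −0.3 and β_extra = −0.3 points/week reproduce group
means moving from 9.2 at baseline to 8.0 (control) and 6.8
(intervention) at week 4 — a calibration preset, not a reproduction of
any participant data. Baseline SDs are not published for this
population; 3.0 between- and 2.5 within-participant points give totals
in the range insomnia screening samples typically show. Diary timing
centers on a 23:30 bedtime and 06:30 wake time with log-normal
sleep-onset latency (median 20 min), truncated-normal WASO (mean 20
min), a 10% missing-day rate, and a 2-point SE gain per completed
restriction week in the intervention arm. Dropout (app-installation
failure) hits the intervention arm at rate 2/62 and removes all
post-baseline data. All randomness descends from one master seed through
named substreams, so rosters, trajectories, and diaries are each
independently reproducible and exports are byte-identical under a fixed
seed.

Rounding and truncation make the generator mildly misspecified relative
to the Gaussian model — intentionally, since real ISI totals are bounded
integers. At the default parameters the induced bias is small (week-4
group means shift by well under 0.1 points; the interaction estimate by
under 0.01/week), which the calibration tests bound empirically.

**Problem sizes.** The verification suite uses 500 replicate trials at
58/56 per arm for parameter recovery of an injected −0.285/week
interaction (mean estimate within ±0.05), 1000 replicates under the null
for the interaction test's type-I error (rejection at α = .05 within
5% ± 2 points), and single 10⁴-per-arm runs for trajectory calibration
(week-4 means within ±0.1 points). These sizes make Monte-Carlo error
comfortably smaller than each tolerance while keeping the suite fast on
one CPU.

**What the simulation does not emulate** — and hence what passing tests
do not show about real data: no circadian physiology (diary metrics and
ISI are statistically, not mechanistically, linked), no floor effects or
skew beyond integer truncation, no informative missingness (diary gaps
are independent of sleep quality), no behavioral feedback from prompts
to diaries, and no secular trends. Parameter recovery on this generator
demonstrates the estimator is correct for its intended model, not that
the model is correct for any particular cohort.

## Known limitations

- The prompt engine's receptive-time handling accepts arbitrary
  non-overlapping window lists but snaps to window edges rather than
  optimizing within windows; "optimal time" is underdetermined.
- The titration adjusts bedtime only; protocols that split adjustments
  across both ends of the window are not represented.
- The eligibility screen implements the listed objective criteria; the
  investigator-judgment criterion ("inappropriate for the study") has no
  computational counterpart.
- The change-score table reports the SPA-minus-control contrast on each
  measure without multiplicity adjustment, matching the trial's stated
  analysis.
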
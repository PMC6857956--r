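---
title: "Smart-schedule blood-pressure telemonitoring: models, rules and design choices"
author: "smartbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart-schedule blood-pressure telemonitoring: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartbp)
```

This vignette is the package's own account of the science it implements:
the monitoring protocol and its rules, the synthetic-cohort model, the
statistics in the analysis layer, and the decisions taken where the
protocol description leaves room. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The monitoring protocol

A patient enrolled on day 0 is prompted (by SMS or automated call,
according to preference) once per day at a configurable hour for 14 days.
The **baseline** is the mean of the chronologically first 5 readings
reported within days 0–13. Everything downstream keys off two-week
half-open windows `[14w, 14(w+1))` anchored at enrollment; they tile the
follow-up exactly, so each reading belongs to one window.

Scheduling is a two-state machine (`daily`, `thrice_weekly`):

* **Window 0** is always daily (the baseline phase).
* **Day 14**: daily iff baseline SBP ≥ 140 mm Hg or baseline DBP ≥ 110
  mm Hg, else thrice-weekly. Both cuts are inclusive ("140 or higher").
* **Each later boundary**: thrice-weekly iff the just-completed window has
  mean SBP < 140 **and** mean DBP < 100; otherwise daily.

Three decisions here were genuinely open:

* *The mixed case.* The stated decrease rule (both means below 140/100)
  and increase rule (both at or above) leave e.g. 139/100 undefined. We
  prompt daily whenever the patient is **not** controlled on both, i.e.
  either elevated mean keeps daily monitoring. A patient with controlled
  SBP but a diastolic mean of 100 is precisely who close monitoring is
  for, so the conservative reading is the clinically safe one.
* *Two diastolic cuts.* The baseline rule uses DBP 110, the ongoing
  biweekly rule DBP 100. The asymmetry is kept as two independent fields
  (`baseline_dbp_daily_cut`, `schedule_dbp_cut`) rather than reconciled;
  a deployment that wants them equal sets them equal.
* *Insufficient baseline and empty windows.* With fewer than 5 baseline
  readings no schedule decision is possible; the patient stays on the
  pre-baseline default (daily). A window with no responses carries the
  current frequency forward — absence of data is not evidence of control.
  Patients who answer nothing during the whole initial daily sequence are
  sent no further prompts at all.

Thrice-weekly prompts go out Monday/Wednesday/Friday at the configured
hour (default 10:00, study-local). The protocol does not pin the three
weekdays; Mon/Wed/Fri spaces measurements evenly and makes schedules
deterministic and testable. All timestamps are naive local datetimes; DST
is deliberately ignored (a one-hour shift is irrelevant at a daily
cadence and would make window arithmetic irreproducible across zones).

**Alerts.** One-time alerts fire strictly outside the closed intervals
90–180 mm Hg (SBP) and 60–110 mm Hg (DBP) — "between 90 and 180" is read
as the closed range being acceptable, so boundary readings do not alert —
plus a biweekly alert when a window's mean DBP is strictly above 100
mm Hg. One reading can raise several alerts. All cut-offs live in
`threshold_config()`; nothing is inlined.

**Triage.** The biweekly provider report sorts patients by descending
period mean SBP, ties by descending mean DBP, then patient id; patients
with no responses are listed last, flagged, rather than dropped — a silent
patient is information.

## Message parsing

Readings arrive as free text. The accepted grammar is two integers joined
by `/`, a comma, the word "over" (case-insensitive) or whitespace, with
surrounding text tolerated; the first number is systolic. Values must be
integers with SBP in 50–300 mm Hg, DBP in 30–200 mm Hg, and SBP > DBP.
The bounds are plausibility bounds, not alert bounds: wide enough to keep
a genuine hypertensive urgency (220/130 parses fine), narrow enough to
reject transposed or truncated nonsense.

Two refusals are deliberate. Separator-free digit runs (`"12080"`) are
*not* heuristically split: 120/80 and 12/080 and 1/2080 are all
consistent with the string, and a silent mis-parse that triggers (or
suppresses) an alert is worse than a re-prompt. Decimals are rejected for
the same reason — keypad self-report produces integers, and a decimal
point usually signals a garbled message. The parser is total: any byte
string yields `ok`, `invalid_format` or `implausible`, never an error.

## The synthetic cohort model

`simulation_params()` describes a cohort; its defaults are the study
conditions the package is built around: 174 consenting patients followed
12 weeks, 58.6% on SMS, a high-baseline stratum (probability 28/130)
centred at 147.3/82.4 mm Hg with a programmed 12-week change of
−10.8/−6.6 mm Hg, a controlled stratum at 125.2/74.8 mm Hg with no drift,
and a 44/174 mass of patients who never answer at all.

Per patient `i`, everything is drawn from a generator seeded by
`(seed, i)`, so any patient can be regenerated alone and the whole cohort
is byte-identical across runs:

* stable level = stratum mean + Normal(0, `between_patient_sd`) offset
  (default 10 mm Hg, drawn independently for SBP and DBP);
* reading = level + drift·ramp(day) + Normal(0, `within_patient_sd`)
  (default 8 mm Hg), rounded to an integer as a keypad would;
* adherence: each prompt is answered with a per-patient probability drawn
  once from Beta(3.9, 2.1) — mean 0.65, SD 0.18 — zero-inflated by the
  never-responder mass. Adherence is constant over time; a time-decay
  could be layered on, but the aggregate rates the model is calibrated to
  do not identify one;
* with probability `p_malformed` (default 0.02) the response string is
  corrupted (separator dropped, value truncated, or free text), so the
  parsing stage has real work on every simulated cohort.

Between- and within-patient SDs are conventional home-monitoring values,
kept configurable, as the aggregate study summaries do not identify them.

**Shape of the programmed decline.** The drift multiplier `ramp(day)` is
0 through the 14-day baseline phase, rises linearly through week 10, and
is 1 throughout the final fortnight. A straight line from day 0 would
contradict the baseline construction: the baseline is measured during
days 0–13, so any decline inside that window leaks into the baseline and
the baseline-versus-final-fortnight contrast would systematically
under-measure the programmed change by the fraction of the line both
summaries straddle (~13% here) — making "the pipeline recovers the
programmed drift" false by construction, not by any defect in the
estimator. With the ramp, the expected baseline equals the stable level,
the expected final-fortnight mean equals level + drift, and the
day-0-to-day-83 reading difference still equals the drift exactly.

**Feedback loop.** The simulator does not fix prompt days in advance: it
calls the engine's own rules (`initial_frequency()`,
`biweekly_frequency_update()`, the Mon/Wed/Fri day generator) on the
readings it has just produced, window by window. Elevated patients
therefore accumulate daily prompts and controlled patients thrice-weekly
ones, with adherence and noise feeding back into the schedule — the
property that makes the response-rate-by-stratum comparisons meaningful.

What the simulator does *not* emulate: treatment mechanisms (the decline
is programmed, not a drug-response model), circadian or seasonal BP
variation, informative dropout, digit preference in self-report, and any
correlation between adherence and BP level. Tests passing on simulated
cohorts show the engine and pipeline are correct under this model; they
are silent on how real patients behave.

## The analysis layer

* **Inclusion**: ≥5 baseline-phase readings and ≥2 readings in the final
  fortnight (weeks 11–12). "Final" per-patient values are means over all
  final-fortnight readings.
* **Stratification**: measured baseline SBP ≥ 140 mm Hg (inclusive)
  versus below.
* **Paired comparisons** use the paired Student t (via `stats::t.test`)
  on unrounded patient-level means; displayed p-values floor at `<.001`
  with raw values kept in machine output. Degenerate zero-variance
  differences are handled explicitly (p = 1 if the mean difference is 0,
  `<.001` otherwise) rather than erroring mid-report.
* **Unpaired comparisons** default to the equal-variance Student test
  (Welch is an option); Pearson correlation via `stats::cor.test`, with
  zero-variance input signalled as undefined rather than returned as 0.
* **Odds ratio**: the sample cross-product ad/bc, reported to 1 decimal,
  with a Woolf log-interval and an exact conditional two-sided p computed
  by summing hypergeometric probabilities of all tables (with the
  observed margins) no more probable than the observed one, with a 1e-7
  relative tie tolerance. The cross-product (not the conditional-MLE
  estimate `fisher.test()` reports) is what such studies print. With a
  zero cell, 0.5 is added to every cell and the result flagged. The
  Woolf interval is documented as such; exact-style intervals from other
  software will differ, and the package does not chase any particular
  one. The test suite verifies the p-value against an independent
  binomial-coefficient enumeration on every table with n ≤ 40 (at 1e-12)
  and against `stats::fisher.test` on random tables.
* **Flow counts** assert their stage inequalities (consented ≤ contacted,
  channel counts add up, analyzable ≤ baseline completers ≤ consented)
  instead of trusting them.

One analysis choice deserves emphasis. The drift-recovery check —
"does the pipeline's 95% CI cover the programmed −10.8 mm Hg?" — is run
with the *simulator's true stratum labels* (`table1_comparisons(by =
"true")`). Stratifying on the measured baseline, as the reported analysis
does, mixes the strata (with group means 22 mm Hg apart and 10 mm Hg
between-patient SD, roughly a quarter of each tail crosses the 140 cut)
and adds regression to the mean from selecting on a noisy baseline. Those
are real phenomena of the published analysis design, faithfully present
in `table1_comparisons(by = "measured")` — but they are properties of the
*design*, not estimator defects, so the calibration check must not be
confounded by them.

## Problem sizes and numerical conventions

The validation suite runs the alert rules against an independent
inequality oracle on 10^5 random readings, the schedule invariants on a
1000-patient simulated cohort, Fisher-p enumeration on all ~1.3×10^5
tables with n ≤ 40, drift recovery on 100 replicate 1000-patient cohorts
(expecting ≥90 covering CIs), and paired-t type-I calibration on 1000
null datasets of 20 pairs (accepting 3.5–6.5% rejection). These sizes
give comfortable Monte-Carlo margins for the bands asserted: e.g. the
nominal 95% coverage makes 100-replicate counts below 90 roughly a
4-in-10,000 event, and the type-I band is about ±2.2 binomial SDs around
0.05.

Conventions, in one place: window intervals are half-open `[start, end)`;
baseline uses the first 5 readings by timestamp with same-day duplicates
retained (duplicates also all enter window means); "or higher" cuts are
inclusive while "more than" alert cuts are strict; triage ties break by
DBP then id; CSV files are RFC-4180 with ISO-8601 timestamps; doubles
stored in CSVs are rounded at generation (4–6 decimals) so write∘read is
the exact identity; and every random quantity in the simulator descends
from `(seed, patient_index)`, never from global RNG state.

## Limitations

The engine executes the protocol; it does not model what providers do
with alerts, medication changes, or any control arm — with no comparison
group, before/after changes must not be read causally. Satisfaction
responses are simulated from a fixed categorical distribution and only
exercise the summary code. The parser's grammar is a documented decision
about plausible self-report formats, not an inference about any deployed
system's actual traffic.
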
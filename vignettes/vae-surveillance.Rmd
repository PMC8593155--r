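---
title: "Automated ventilator-associated event surveillance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ventilator-associated event surveillance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaesurv)
```

## The surveillance problem

Ventilator-associated pneumonia surveillance based on clinical criteria is
subjective and hard to reproduce. The CDC NHSN ventilator-associated event
(VAE) framework instead defines events purely from daily ventilator
settings and routine laboratory values, in tiers:

* **Tier I — ventilator-associated condition (VAC):** worsening
  oxygenation after a baseline period of at least two days of stable or
  decreasing ventilator support, operationalised as a sustained rise of
  the daily minimum PEEP by ≥ 3 cmH2O or of the daily minimum FiO2 by
  ≥ 0.20.
* **Tier II — infection-related VAC (IVAC):** a VAC accompanied, within two
  days of onset, by abnormal temperature or white-cell count together with
  a newly started antimicrobial agent continued for at least four
  qualifying days.

Tier III (possible pneumonia) needs microbiology and respiratory-secretion
data and is out of scope for this package.

Because the rules are numerical, the whole surveillance can be run
retrospectively over years of patient-data-management-system (PDMS)
records. Two practical obstacles dominate, and they shape this package:
the PDMS often has *no explicit mechanical-ventilation variable*, and the
raw respiratory signals contain *artefacts and set-point oscillation* that
corrupt daily minima.

## Pipeline and assumptions

### Ventilation episodes from etCO2 continuity

End-tidal CO2 is only measured while a patient is connected to a
ventilator, so continuous etCO2 availability is the ventilation proxy:
timestamps are partitioned into maximal runs whose consecutive gaps do not
exceed `etco2_max_gap_minutes` (default 6 min, i.e. at least one
measurement per 6-minute window). We formulate this as a *consecutive-gap*
rule rather than a window-grid rule because the latter depends on an
arbitrary grid origin; up to that phase the two are equivalent. An episode
spans its first to last etCO2 timestamp — conservative in that trailing
ventilated minutes after the last measurement are not counted.

Following the CDC episode convention, reintubation on the same or next
calendar day continues the episode: consecutive episodes merge unless at
least `episode_merge_gap_days` (default 1) complete ventilator-free
calendar days separate them, and day numbering continues from the first
component. MV day 1 is the calendar day ventilation begins.

Device days (the incidence denominator) use the noon rule: an admission
contributes one ventilator day on a date when an episode overlaps that
date's `[11:00, 13:00)` window by a positive duration. All ventilated
admissions count toward the denominator, including those ventilated fewer
than the 4 calendar days an event needs. Non-invasive ventilation cannot
be distinguished without an artificial-airway variable and is not
modelled; in ICUs that cap non-invasive ventilation below ~48 h this
inflates only the denominator, not event detection.

### Cleaning

Order matters, and is: (1) temperature range filter, (2) restriction of
FiO2/PEEP to ventilation episodes, (3) per admission-day low-outlier
exclusion, (4) physiological flooring, then the daily minimum. Flooring
comes *after* exclusion deliberately: flooring first would lift artefacts
(e.g. an FiO2 recorded as 0.21 while circuits are flushed) onto the floor
and silently convert them into plausible daily minima.

The low-outlier rule removes the `k = floor(p * n)` smallest of the day's
`n` values (default `p` = 0.05). `floor`, not `ceiling`: with sparse
manual series (`n < 1/p`) nothing is removed, which protects days with a
handful of measurements; with a 2-minute cadence (`n ≈ 720`) `k ≈ 36`, far
above the handful of artefacts a day realistically contains. We use the
lowest surviving value rather than the CDC's "value stable for one hour"
because the latter is ill-defined on irregular high-frequency data; this
is the one deliberate deviation from the protocol text and it is what the
sensitivity analyses in the test suite probe.

Temperature uses an absolute plausibility band instead (values strictly
below 35 °C or strictly above 42 °C are excluded; the bounds are kept), and
temperature/WBC extremes pool *all* calendar-day measurements from all
concurrent sources — only FiO2/PEEP are restricted to ventilation periods.

### Tolerance for set-point oscillation

Measured FiO2 and PEEP oscillate around the set value (a set FiO2 of 0.60
measured as 0.58), so a genuine one-threshold rise can be measured
fractionally short. The protocol texts never state algebraically how a
"tolerance" should modify the threshold, and two readings are defensible:

* **shrink-threshold** (default): the required rise becomes
  `threshold * (1 - t)` — a near-threshold rise still qualifies;
* **baseline-allowance** (`tolerance_mode = "baseline_allowance"`): the
  full rise is required, but the second baseline day may exceed the first
  by up to `t * threshold` and still count as stable.

Both are implemented; the shrink form is the default because the
motivating failure mode is a measured rise falling just short of the set
point. On coarse, artefact-free daily minima the two coincide, which is
why published sensitivity analyses can find no difference between
tolerances of 0, 10 and 20%.

### Detection

A candidate onset day `d` needs MV day ≥ `earliest_onset_mv_day` (3), a
stable baseline (`value(d-1) ≤ value(d-2)`, both ventilated and measured),
and a sustained rise: `value(d) − ref ≥ τ` **and** `value(d+1) − ref ≥ τ`.
The reference `ref` is the day `d−1` minimum (`baseline_reference =
"second_day"`): under the stability condition it is the lower of the two
baseline days, hence the harder, more conservative reference; the
`"first_day"` alternative is a configuration switch. Missing data never
satisfies a condition — a day without a PEEP value can neither establish a
baseline nor a rise.

PEEP is checked before FiO2; when both fire on one day this affects only
the `criterion` label, never the event count. After an onset `o`, the next
eligible onset is `o + event_washout_days` (14; day `o` counts as day 1 of
the event period). IVAC evidence scans the `[o−2, o+2]` window day by day
(fever, hypothermia, leukocytosis, leukopenia order within a day) and
takes the first agent, ordered by start date then name, whose qualifying
days reach `min_qad` (4). A "new" agent is one not administered on either
of the two days before its start; single-day gaps inside a course are
bridged and count toward its length; a gap of two or more days ends it.

### Statistics

Validation uses plain confusion-matrix metrics at the admission level.
Incidence is events per 1000 ventilator days with the exact Garwood
interval from chi-square quantiles — chosen over normal approximations
because yearly strata can be small, and fixed as *the* interval method of
the package since published rate CIs in this literature rarely state
theirs. The yearly trend is the Poisson log-linear model
`log E[events_y] = β0 + β1 year + log(device_days_y)` fitted by IRLS
(`stats::glm`, relative deviance change < 1e-10, ≤ 100 iterations);
`exp(β1)` is the yearly incidence rate ratio. Year enters as a continuous
covariate — a categorical coding could not yield a single yearly ratio.
Wald intervals and p-values are reported (a likelihood-ratio p is included
as `p_lrt`); no overdispersion modelling, matching standard practice for
these small yearly tables.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `low_outlier_fraction` | 0.05 | fraction/day | removes sporadic low artefacts from dense series; 0 disables |
| `tolerance`, `tolerance_mode` | 0.10, shrink | fraction | absorbs set-point oscillation of measured values |
| `peep_increase_threshold` | 3 | cmH2O | CDC worsening threshold |
| `fio2_increase_threshold` | 0.20 | fraction | CDC worsening threshold |
| `fio2_floor`, `peep_floor` | 0.30, 5 | fraction, cmH2O | protocol floors for daily minima |
| `temp_exclude_below/above` | 35, 42 | °C | plausibility band, strict exclusion |
| `fever_above`, `hypothermia_below` | 38.0, 36.0 | °C | IVAC temperature bounds |
| `wbc_high`, `wbc_low` | 12.0, 4.0 | 10³/µL | IVAC white-cell bounds (≥ / ≤) |
| `etco2_max_gap_minutes` | 6 | min | ventilation-continuity proxy |
| `noon_window` | 11:00–13:00 | clock | device-day rule, half-open |
| `min_qad` | 4 | days | antimicrobial-course requirement |
| `event_washout_days` | 14 | days | one event per 14-day period |
| `earliest_onset_mv_day` | 3 | MV day | 2 baseline days must precede onset |
| `episode_merge_gap_days` | 1 | days | reintubation continues the episode |

## The synthetic ICU

`generate_cohort()` emulates what the detector consumes, and nothing more:

* cadences of the source system — FiO2 and etCO2 every 2 min, PEEP every
  15 min, temperature once per 8-h shift, WBC daily;
* ventilation durations with median 1 day and interquartile range 1–3
  (typical of a mixed surgical/medical ICU), truncated at 30 days. A pure
  geometric law cannot have median 1 *and* upper quartile 3, so an
  explicit discrete head (P(1) = 0.55, P(2) = 0.15, P(3) = 0.12) with a
  geometric tail is used, with the head masses chosen to keep the sample
  quantiles away from knife edges;
* set-point trajectories: baseline FiO2 in 0.30–0.50, PEEP in {5, 6, 8};
  an embedded VAC holds them stable and then raises one criterion above
  its threshold from a random onset at MV day ≥ 3, sustained to the end of
  ventilation; an embedded IVAC adds a fever (38.6 °C) or leukocytosis
  (14.5) day within one day of onset plus a five-day course of a new
  agent. Ground truth is thus defined by construction, never by running
  the detector — validation cannot be circular;
* measurement noise: relative oscillation around the set point
  (`oscillation_sd`, default 2%) recorded at device resolution (FiO2 0.01,
  PEEP 0.5 cmH2O, temperature and WBC 0.1), and downward artefacts
  replacing each respiratory value with probability `artefact_rate`
  (default 1%) by a low spike (FiO2 → 0.21, ambient air; PEEP → 0).
  Artefacts are downward only, because only low values can corrupt a
  recorded daily minimum;
* default event prevalence `vac_fraction` = 0.025 of admissions (events
  are embedded only in admissions ventilated ≥ 4 days, redrawing the
  duration when needed), with 35% of them IVAC — the event mix of a large
  general-ICU cohort. The artefact stress test in the suite instead uses a
  *validation-style* cohort with `vac_fraction` = 0.33, mirroring the
  enriched long-ventilation convenience samples used for diagnostic
  validation studies.

What it does **not** emulate: real ventilator weaning dynamics, correlated
multi-day artefact bursts, non-invasive ventilation, agent changes within
a treatment episode, missing-data patterns of manual charting, or any
physiology beyond the criteria variables (no SpO2, no ventilator modes).
Passing the closed-loop tests therefore shows the *algorithm* is faithful
to the definitions, not that its accuracy on real PDMS data equals the
synthetic one.

## Numerical choices and degenerate inputs

* Decimal thresholds (0.20) are not binary-representable; detector
  comparisons carry a 1e-9 slack so an exactly threshold-sized rise
  qualifies. All boundary comparisons are as the definitions read them:
  rises use ≥, temperature exclusion and fever use strict inequalities,
  WBC bounds are ≥ / ≤.
* Timestamps are naive local clock time (carried as UTC internally so day
  arithmetic never crosses DST); calendar day = local date; antimicrobials
  are date-granular because the IVAC rules operate on days.
* Displayed rates are rounded to 1 decimal and proportions/IRR to 2, half
  away from zero (reporting convention); all stored values are exact.
* Degenerate inputs: an empty measurement file yields an empty, valid
  result; a day with no in-episode respiratory values has an absent
  minimum (never imputed); an all-artefact temperature day has absent
  extremes; a metric with a zero denominator is flagged undefined rather
  than fabricated; a single incidence stratum skips the trend.
* FiO2 entered as percent (value > 1) is normalised to a fraction on read;
  a single internal unit prevents threshold bugs between "20% FiO2" and
  "0.20".

## Problem sizes in the test suite

The suite checks the detector against an independent brute-force
day-by-day oracle on 1000 random summary sequences (≤ 30 days), exact
closed-loop recovery on a zero-noise 200-admission cohort, Monte-Carlo
coverage of the exact Poisson interval on 2000 replicates, slope recovery
of the trend model on 500 simulated nine-year cohorts, and the
direction-of-effect stress test (5% cleaning vs none under 1% artefacts)
on a 120-admission validation-style cohort. These sizes make the full
suite run in well under a minute while leaving the statistical assertions
comfortable margins.

## Known limitations

* Tier III (PVAP) is not implemented (needs microbiology data).
* The etCO2 proxy counts non-invasive ventilation as ventilation;
  institutional context must justify the denominator interpretation.
* The daily minimum is the lowest surviving value after percentile
  exclusion, not the CDC's one-hour-stable value; results are calibrated
  to dense automatic sampling and the appropriate `low_outlier_fraction`
  may differ across monitor hardware.
* Admission-level validation metrics do not check onset-date agreement;
  the closed-loop tests do compare exact onsets, tiers and criteria.
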
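---
title: "Scoring simulator driving errors and a synthetic training cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring simulator driving errors and a synthetic training cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivescore)
```

## What this package models

Driving-simulator training programs for older drivers with mild cognitive
impairment (MCI) score a fixed route in real time and play an auditory
feedback message whenever one of a small set of rules is broken: speeding,
tailgating, weaving, omitting the turn signal or the blind-spot check at a
lane change, rolling through a stop sign, skipping the left-ahead-right
visual search at a stop-sign intersection, or mishandling a red light.
Counting these errors per session gives a per-driver learning curve over
repeated sessions, and a delayed, feedback-free recall session probes
whether the trained improvement is retained.

`drivescore` re-implements that measurement chain offline, in four layers:

1. a **scenario** (`build_reference_scenario()`): the static route shared
   by the detectors and the generator;
2. a **detection engine** (`run_engine()`): eight rule-based detectors run
   over recorded telemetry, with re-warning windows and a feedback
   refractory period;
3. a **synthetic cohort generator** (`generate_compliant_run()`,
   `sample_injection_plan()`, `apply_injections()`, `run_study()`):
   compliant baseline trajectories into which rule violations are injected
   with exact count control, following a session learning curve and a
   recall rebound;
4. the **statistics** (`friedman_test()`, `wilcoxon_paired_test()`,
   `ks_two_sample()`, `analyze_study()`): the nonparametric
   repeated-measures analysis of the resulting error table.

Because no human data ship with the package, every cohort-level quantity
is a calibrated-simulation round trip: the generator plants a known ground
truth, the engine must recover it, and the statistics must recover the
designed population pattern.

## The reference scenario

The packaged route is 27.48 km long and tiles into nine speed-zone
subsections totalling 650 m at 35 km/h, 12,570 m at 50 km/h and 14,260 m
at 70 km/h. Only the totals are fixed by the design being emulated; the
interleaving (slow urban segments wrapped around stop-sign clusters,
alternating 50- and 70-km/h stretches elsewhere) is this package's own
fixed, deterministic layout. Positions are metres from the route origin
and zone intervals are half-open `[start, start + length)`, so every
position belongs to exactly one zone.

The route carries 15 lane-change prompts (seven overtake pairs, each a
left change followed by a right change 400 m later, plus one merge),
8 stop-sign and 4 traffic-light intersections, and 5 lead-vehicle
episodes. The intersection counts are a design choice — enough events per
run for stable per-session counts — since only their presence, not their
number, is fixed by the emulated design.

Two geometric defaults are linked: `lane_width = 3.5` m and
`vehicle_width = 1.975` m. The weaving rule fires beyond 17.5% of the lane
width from the lane centre, i.e. 0.6125 m; with these widths that is
exactly the offset at which the nearest tire sits 15 cm from the lane
line (3.5/2 − 0.6125 − 1.975/2 = 0.15 m), so the two standard phrasings
of the weaving criterion coincide.

Traffic lights run a 30 s green / 4 s yellow / 20 s red cycle. Each
light's phase offset is set so that the *nominal* compliant arrival falls
8 s into red. This has two useful consequences: a compliant driver
deterministically stops and waits for green at every light (realistic,
and trivially legal under the permissive yellow rule), and every light is
a feasible site for injecting a red-light violation (the injected driver
simply fails to wait).

## Detection rules and conventions

All thresholds live in `detection_config()` and are **strict inequalities
on the violating side**: a speed of exactly limit + 10 km/h, a headway of
exactly 2.0 s, an offset of exactly 17.5% of lane width are compliant.
The defaults are:

| rule | threshold | persistence / window |
|---|---|---|
| speeding | > limit + 10 km/h | re-warning every 10 s while violating |
| tailgating | headway < 2 s | re-warning every 10 s while violating |
| weaving | \|offset\| > 17.5% of lane width | sustained ≥ 10 s |
| complete stop | speed < 1 km/h | sustained ≥ 1 s, within 30 m before the line |
| signal / blind spot | correct signal; \|yaw\| ≥ 45° toward the turn | within 3 s before the lane-boundary crossing |
| visual search | yaw ≥ +30°, ≤ −30°, and an ahead return | on the 30-m approach to the stop line |
| red light | red at the intersection midpoint after entering on yellow or red | — |

Notes on the less obvious choices:

* **Tailgating** uses time headway — lead gap divided by the follower's
  own speed — rather than a closing-speed time-to-collision. The
  standard worked number confirms this reading: at 50 km/h a 2-s headway
  is 2 × 50/3.6 = 27.78 m. A standing vehicle has undefined headway and
  is treated as compliant.
* **Re-warnings count as errors** by default: a violation that persists
  through the 10-s grace window records an additional error each window.
  Whether the original tallies counted re-warnings is not documented;
  `detection_config(count_rewarnings = FALSE)` switches to one error per
  episode.
* **Head-yaw thresholds** (45° for the blind-spot check, 30° for the
  visual search, a 3-s window and a 30-m approach) are this package's
  defaults: the behaviour, not an exact angle, is the construct being
  scored, and the original instrument used a camera-based module whose
  parameters are not reproduced here. All four are config-exposed.
* **Weaving exemption:** samples within ±2 s of a lane-boundary crossing
  are exempt from the weaving rule, since a lane change necessarily
  leaves the lane centre.
* **Timestamping:** continuous-rule errors are stamped at the violation
  onset (re-warnings at each re-warning instant); weaving errors when the
  10-s persistence completes; intersection-level errors at the sample
  where the vehicle clears the intersection. Stopping beyond the line at
  a red light is tallied under the traffic-light kind.
* **Refractory:** after any emitted feedback, further feedback is
  suppressed for 7 s, but suppressed errors are still recorded — counts
  are exactly invariant to the refractory, only the `feedback_emitted`
  flags change.

The engine is sampling-rate agnostic: every rule works from timestamp
differences, and resampling a run from 20 Hz to 40 Hz changes no count
(this is a tested property).

## The synthetic cohort

`generate_compliant_run()` builds a run that breaks no rule: cruise at
the zone limit with 1.5 m/s² comfort envelopes (computed on a 2-m
position grid, then sampled at 20 Hz by default), full 1.6-s stops with a
+40°/0°/−40° scan at stop signs, waits for green at lights, signalled and
blind-spot-checked changes at all 15 prompts, a ≥ 3-s headway under lead
vehicles, and lateral noise from a discretised mean-reverting (AR(1),
2-s time constant, 0.15 m stationary SD) process clipped at 70% of the
weaving threshold. The zero-error property of this baseline is asserted
per kind in the test suite.

Errors are then *injected*, not emergent: `sample_injection_plan()` draws
a per-kind count from a Poisson law and assigns each violation a valid,
well-separated site; `apply_injections()` locally rewrites the stream so
that each site violates exactly its rule with magnitude at least 1.2
times the threshold (e.g. speed raised 5 km/h past the grace, a 12-s
offset excursion at 1.3× the weaving threshold, a rolling stop at
3 km/h). Injected counts are recovered exactly by the engine — the
round-trip identity is tested across seeds and sessions — which is what
makes the cohort a usable measurement standard. Draws exceeding the
available sites (more stop-sign errors than stop signs) are truncated
with a warning; at the default rates this trims the expected session-1
total by well under 0.05 errors.

The learning model is multiplicative: session-*j* means are
`base_rate × learning_factor^(j−1)`, and the recall mean is
`base_rate × (rebound + (1 − rebound) × learning_factor^(n−1))`. The
defaults are calibrated to the study conditions being emulated: per-kind
session-1 rates of 4.0 (speeding), 1.7 (signal omission) and 1.1
(tailgating) are anchored values; the remaining kinds (weaving 4.5,
blind spot 3.0, stop control 3.0, visual search 3.8, red light 0.5) are
calibration choices that bring the session-1 total to exactly 21.6
errors per driver. `learning_factor = (8.2/21.6)^(1/4) ≈ 0.785` makes
the session-5 expectation 8.2, and `recall_rebound = 1` models complete
loss of the trained improvement, returning the recall expectation to the
baseline 21.6.

`run_study()` executes the full chain — 15 drivers × (5 sessions +
recall) = 90 generated, injected and scored runs — in about half a
minute. For replicate-level work, `simulate_error_table()` draws the
per-run counts with *the same seeds and RNG path* as the full pipeline
(the counts are the first draws under each run's plan seed) and skips
telemetry synthesis; its output is bit-identical to the full pipeline's
error table, an equality that is itself tested. The packaged statistical
pattern check uses 100 such count-level replicates plus one complete
90-run telemetry study.

## Statistics

The error table is drivers × sessions × kinds. `analyze_study()` runs,
for each kind and for the totals, a Friedman test across the training
sessions and three paired contrasts: last training session vs first,
recall vs last, recall vs first.

* **Friedman**: within-block mid-ranks, the classical tie-corrected
  chi-square, p from the χ²(k−1) law; `exact = TRUE` enumerates all
  `(k!)^n` within-block orderings for `n·k ≤ 12`.
* **Wilcoxon**: the session contrasts are within-subject, so the
  signed-rank form is the default (the rank-sum name is often used
  loosely for this design; a true independent-samples rank-sum is
  available via `paired = FALSE`). Zero differences are dropped before
  ranking, tied absolute differences get mid-ranks, the p-value is exact
  (all `2^n` sign patterns) up to 12 non-zero differences and otherwise
  a tie-corrected, continuity-corrected normal approximation. Two-sided
  exact p is twice the smaller tail, capped at 1.
* **Kolmogorov–Smirnov** (for subgroup comparisons): D is the sup
  distance between ECDFs; the p-value is exact by lattice-path counting
  conditional on the pooled sample (tie-aware) for `m·n ≤ 100`, else
  asymptotic.

All three implementations are verified in the test suite against
brute-force enumeration oracles and against the corresponding base-R
tests where their conventions coincide. No multiple-testing correction
is applied — raw two-sided p-values at α = 0.05 — and the results table
records this in its metadata.

With the default calibration the designed population pattern is: a
strongly significant Friedman effect on totals over sessions 1–5,
a significant recall-vs-session-5 increase, and a non-significant
recall-vs-session-1 difference. The packaged check requires this joint
pattern in at least 90 of 100 seeded replicates; the recall-vs-session-1
contrast is a true null (both sessions draw from the same Poisson means),
so its ~5% false-positive rate is the binding term.

## Numerical choices and degenerate inputs

* Positions half-open, 0-based metres; `zone_at()` raises a bounds error
  at `total_length` itself.
* Telemetry CSVs are written in shortest round-trip representation and
  parsed with base R's exact reader, so write-then-read is bit-lossless.
* Error ties at the same timestamp are ordered by the canonical kind
  order before the refractory pass.
* Degenerate statistics (constant matrices, all-zero differences,
  identical samples) return `p = 1` with a `degenerate` flag rather than
  an error; an all-missing block is an error.
* Seeds: every stochastic step takes an explicit seed; per-run seeds
  derive arithmetically (below 2³¹) from the design's master seed, so
  studies, pipelines and their CSV outputs are byte-reproducible.

## What the generator does not emulate

The synthetic cohort is a measurement standard, not a behavioural model.
It does not reproduce psychophysically realistic steering or braking
dynamics, speed variability (the compliant driver tracks the limit, so
the simulated drive is somewhat faster than a human's), driver attrition
at recall (the default design keeps all 15 drivers, which keeps the
Friedman blocks balanced; a real cohort lost two), within-driver
heterogeneity in learning rates, or correlations between error kinds.
Passing tests therefore demonstrate that the *measurement chain* —
detection, tabulation, statistics — is correct and that the designed
learning/retention pattern is recoverable at the designed effect sizes;
they do not validate the behavioural realism of the trajectories.
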
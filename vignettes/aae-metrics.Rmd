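---
title: "A priori metrics for AAE decompositions: model, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A priori metrics for AAE decompositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaemetrics)
```

## The model and its assumptions

An AAE decomposition is a three-level structure: activities own sets of
actions, actions own sets of sensor events. Events are atomic binary-sensor
observations — a rising or falling edge of a door contact, outlet or flow
sensor, or a PIR presence pulse — identified by their verbatim label
(conventionally `"Zone|Sensor|Signal|Edge"`). The package never parses the
label: every metric is purely set-theoretic, so event identity is exact
string equality.

Two modelling switches matter:

* `allow_shared_actions` (default `FALSE`): the working assumption is that
  an action belongs to exactly one activity. All metrics are nevertheless
  defined for the shared case — `CA(aj)` counts owners, `Sa` becomes
  non-trivial, `F(aj|Ai) = 1/CA(aj)` drops below 1 — and the validator
  only enforces uniqueness when the flag is off.
* `weighted_edges` (default `FALSE`): a movement recurring within an
  action gives its event a multiplicity. Multiplicities affect **only the
  weight family** (numerator = multiplicity, denominator = total mass of
  the action); the participation counters remain set-membership counts,
  because they are defined through set intersections. Distinguishability
  likewise averages over the *distinct* events of an activity.

An incidence fixture (`incidence_fixture()`) is the activity-level
projection of a decomposition: the matrix of `Ca(ek|Ai)` counters plus the
action-to-activity map. It supports every activity-level metric (`Ca`,
`CA`, `F`, `De`, `Da`, pairwise `Se`/`Sa`); metrics that need to know
*which action* an event sits in — `Se(aj|ak)` and all weights — raise an
explicit "requires a full decomposition" error rather than guessing. On
random decompositions the projection is exact: tests verify that every
supported metric agrees between a model and `as_incidence_fixture()` of it.

## Exact arithmetic and rounding

Distinguishability is a mean of small fractions. Rounding the per-event
contributions first and averaging the rounded values gives a different
second decimal than rounding the exact mean (for the embedded case study,
0.68 instead of 0.69 for the cooking activity), so all sums and means run
over exact numerator/denominator pairs and conversion to double happens
last. Display rounding is half-up (`round_half_up()`), applied to the
exact fraction where one is available; base R's round-half-to-even would
disagree on exact boundaries such as 27/40.

Degenerate inputs are handled as follows: an event present in the
universe but used by no action has all counters 0 and **no** elementary
contribution (error `"event unused"`, not 0/0); empty activities or
actions are validation errors; membership violations (asking for
`W(ek|aj)` of a foreign event) are errors, while `F(ek|Ai)` and
`W(ek|Ai)` extend to 0 for events of *other* activities, matching how
published tables print those cells.

## The embedded case study

The fixture transcribes the published event-by-activity table of a
two-room instrumented flat: 38 rows against AC (cooking), AHBP
(hot-beverage preparation) and APH (personal hygiene; the alias ATCPH
appears in some published row labels), with two actions per activity and
none shared. Transcription conventions:

* Two row labels are printed twice (`Bathroom|Sink_waterflow|Flow|1`,
  `Kitchen|Coffee_machine|Power|1`, plausibly typos for the missing `|0`
  falling edges). They are kept as 38 distinct rows with `"#1"`/`"#2"`
  suffixes: every metric depends on row distinctness only, never on the
  label text.
* The accompanying narrative counts 39 used events where the table prints
  38 rows; the fixture is the table as printed, and the discrepancy is
  simply recorded here.
* The event-to-action assignment within each activity is published only
  graphically, so the fixture carries activity-level counters; weights
  are therefore not computable from it (see above).

The sensor inventory (`case_study_inventory()`) reproduces the available
instrumentation arithmetic: 8 door sensors × 2 + 3 door/PIR sensors × 3 +
5 outlets × 2 + 4 flow sensors × 2 = 43 events.

```{r}
fx <- case_study_fixture()
metric_tables(fx)$activity
```

## Analyzer thresholds

The metric families come with no universal acceptance levels: what counts
as "distinguishable enough" depends on the number of activities and how
events are spread, and is best set per activity. The analyzer therefore
takes every cutoff from an explicit configuration:

| parameter | default | role |
|---|---|---|
| `distinguishability_floor` | 0.8 | flag activities with De or Da below |
| `sharing_ceiling` | 0.5 | flag activities sharing more than half their events/actions with another |
| `contribution_floor` | 0.5 | drill down to elements contributing less |
| `weight_ceiling` | 0.1 | call a shared event "heavy" above this weight |

The defaults are pragmatic: a majority-sharing activity (over half its
events seen elsewhere) is worth a look, as is one whose mean contribution
falls below 0.8 — levels at which the case study's two kitchen activities
are flagged while the fully separable hygiene activity passes, matching
the qualitative reading of the tables. All four can be overridden
globally or per activity (`overrides`), and every flag records the exact
comparison that triggered it, so reports are auditable. Flagging is
monotone in the thresholds (raising the floor or lowering the ceiling
never un-flags), and reports are pure functions of (input, config): the
JSON rendering is byte-identical across runs.

Recommendation codes are a closed enumeration of diagnostic patterns, the
central one being `HIGH_PARTICIPATION_HIGH_WEIGHT`: an event involved in
several activities, sitting in a single action here, and carrying a large
weight — the textbook case where adding events to the action dilutes the
weight and restores separability. Severity is reported as the raw margin
to the threshold; no additional scale is invented.

## The synthetic generator and stream simulator

`generate_decomposition()` emulates small instrumented-home studies. Its
defaults are fixed at the case-study scale — 3 activities, 2 actions
each, a pool of 43 sensor events — with action event-set sizes of 6–14
events (the case-study actions, reconstructed from the published weights,
range from about 6 to 16 events; the upper end is capped at 14, the
largest size compatible with partitioning the 43-event pool into three
per-activity slices). Sharing probabilities default to 0.15
cross-activity and 0.1 within-activity, a moderate regime comparable to
the case study, where 10 of 38 events are shared between two activities.
Each activity draws from a private pool slice unless a draw is designated
shared, so `cross_activity_share_prob = 0` guarantees pairwise-disjoint
event sets — the degenerate limit in which every distinguishability is 1.

`simulate_stream()` builds training-style streams the way experimental
datasets are assembled: scheduled activity realizations concatenated in
order, each realization emitting its action's events (multiplicity times,
optionally shuffled to model step inversions), with noise events inserted
at inter-event gaps as Poisson draws (`noise_rate` is the expected count
per gap) from either all used events or only other activities' events
(wandering into another room). Events are ordinal and untimed: the
metrics are atemporal, so the simulator carries no clock. Interrupting or
parallel realizations can be emulated by interleaving two schedules.

The validation recognizer (`membership_score()`) is deliberately
transparent — the mean elementary contribution over a sliding window —
rather than a learned sequence model: it makes the metric-to-performance
link testable without entangling it with any training procedure.
`false_positive_study()` slides a 5-event window (the sequence length a
realistic recognition stage would use) over noise-free streams and
reports, per ordered activity pair, the fraction of windows scoring
positive. Two properties close the loop, and are enforced by tests:
a pair with zero event-sharing rate has exactly zero cross-activity
positive fraction, and positive fractions appear exactly where sharing is
positive; across a generated ensemble the sharing rate and the
false-positive fraction are positively rank-correlated.

## What passing tests do and do not show

The test suite runs the metric identities (normalization of each weight
family, conservation of contributions, the De ⇒ Da implication on 1000
generated decompositions, projection equivalence) at small problem sizes:
3 activities, 1–3 actions each, 2–5 events per action for the property
loops, and 2 streams × 5-event windows for the prediction-link studies.
These sizes exercise every code path — sharing, disjointness,
multiplicities — while keeping the default test run fast; the identities
are exact, so size only affects coverage, not tolerance. What the
synthetic studies do *not* show: real sensor streams have timing,
missed/phantom events and person-specific variation that the generator
does not model, and the membership score is not a sequence recognizer —
a high distinguishability remains a *necessary-condition* screen, not a
guarantee of deployment accuracy.

## Known limitations

* Fixtures cannot supply weights or action-level sharing; only a full
  decomposition can.
* Actions have no multiplicity within activities (an activity's action
  set is a set); weighted edges exist only between actions and events.
* The analyzer recommends; it does not modify the decomposition or
  optimize sensor placement.
* With shared actions enabled, the per-activity counter sum
  `Σ_Ai Ca(ek|Ai)` can exceed the global `Ca(ek)` (each owner counts the
  shared action once); equality holds exactly in the default unshared
  mode. The implementation asserts this `≥` direction, which follows from
  the definitions.
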
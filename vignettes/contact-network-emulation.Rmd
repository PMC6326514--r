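---
title: "Emulating proximity-tag contact networks in an equine facility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating proximity-tag contact networks in an equine facility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equitag)
```

## The system being modelled

Active RFID proximity tags can log animal, human and location contacts in
agricultural settings where powered readers are impractical: each tag senses
partners within about 2 m once per second and writes contact events to its
own flash memory. `equitag` is a software emulation of such a deployment in
a boarding stable — nine haltered horses, six staff, seventeen static
location tags and one *bookkeeping* tag that sits with whatever tags are
off duty — together with the downstream pipeline that turns the raw per-tag
logs into daily weighted contact networks, node centralities, mixing heat
maps and a survey-vs-tag classification table.

The package has five layers, each usable on its own:

1. **Facility simulator** (`build_scenario()`, `simulate_proximity()`):
   ground-truth per-second in-range indicators driven entirely by the barn
   schedule.
2. **Tag emulator** (`emulate_tags()`): converts the truth stream into
   per-tag event logs with the firmware's exact segmentation, clock, memory,
   battery and restart semantics.
3. **Cleaning pipeline** (`validate_ids()`, `assemble_events()`,
   `to_wall_clock()`, `filter_window()`, `remove_bookkeeping()`,
   `reconcile_duplicates()`, or `clean_contacts()` for the whole chain).
4. **Network analysis** (`aggregate_daily()`, `centrality()`,
   `heatmap_matrix()`, `mixing_summary()`, `load_contact_matrix()`).
5. **Survey comparison** (`build_survey_network()`, `weekly_combined()`,
   `classify_networks()`).

## Contact-event semantics

A *contact event* between two tags opens at the first second the pair
senses each other and remains open while sensing continues. Only after
**30 consecutive silent seconds** (the *washout*) is the event closed.
Consequences the emulator reproduces exactly:

* a silent gap of 29 s or less is absorbed into one event; a gap of 30 s or
  more splits it in two;
* the recorded end time is the **last sensed second**, so the washout
  silence itself is not counted in the duration (the event's duration is
  `end - start` on the recording tag's clock);
* the closing `END` record is physically written when the washout elapses;
  a tag whose battery dies inside that window leaves the session open in
  its log. The cleaning stage closes such orphans at their last `ONGOING`
  record and flags them.

Tags carry no real-time clock, only a counter started at battery insertion.
Both participants log each event on their own counters, so the two
recordings of one physical contact agree in duration but differ in start
time by exactly the difference of insertion offsets. The registry stores
each tag's insertion anchor, and `to_wall_clock()` re-bases all events.

Each stored record occupies 16 bytes; an 8 MiB flash therefore holds
`event_capacity(8 * 1024^2, 16)` = 524,288 records, after which the tag
keeps sensing but stores nothing new. Within one second a tag processes
detected partners one at a time in random order; this affects only the
order of records in memory, which the session-folding stage is insensitive
to.

## What the simulator emulates — and what it does not

The truth generator is schedule-driven; its defaults are the study-week
conditions:

| parameter | default | meaning |
|---|---|---|
| horses / people / static tags | 9 / 6 / 17 (+1 bookkeeping) | 33 tags |
| study length | 7 days, starting Tuesday | first day index 1 |
| turnout window | 08:30–16:30 | halters clustered on the fence hook |
| weekend pasture days | days 4–5 (Fri, Sat) | one horse moves to a fourth pasture |
| stall bouts | exp. on/off, means 1800 s / 7200 s | same-aisle neighbours overnight |
| transits | 60 s | barn door + aisle tag at turnout legs |
| training bouts | p = 0.8/horse/day, mean 2400 s, 17:00–20:00 | arena/wash/groom/cross-tie tag + handler |
| person transits | 4/shift-day, 60 s | entry/exit past static tags |

Two modelling choices deserve emphasis. First, during turnout the halters
hang together on the pasture fence, so all halter tags of a pasture are
*continuously and completely* mutually in range — the simulator enforces a
complete within-pasture graph for every turnout second. This mirrors the
deployment protocol, and it means pasture contact hours measure co-pasturing,
not horse sociality. Second, horse–horse proximity arises *only* from shared
aisles (overnight bouts) and shared pastures (fence hook); training and
transit create horse–location and horse–person contacts only. The
survey-predicted network — the union of complete graphs over pasture classes
and aisle classes — is therefore a superset of any tag-derived horse network
by construction, which is why the sensitivity and negative predictive value
of the survey prediction equal 1 on every simulated week. Real deployments
need not satisfy this confinement (horses can meet across fence lines, in
cross-ties, or during rides), so passing these checks validates the
pipeline's bookkeeping, not the predictive power of surveys on real farms.

Radio physics is deliberately out of scope: the 0.5–6 m detection
variability is reduced to a per-second miss probability (`p_miss`, default
0.05) and an optional per-second spurious-detection probability against a
configured candidate list (default off), echoing anomalies such as two
fixed wall tags recording each other. Weather, battery chemistry and horse
behaviour beyond the schedule are not modelled.

Tag imperfection defaults: insertion offsets uniform on 0–300 s (the
insertion-window bound), battery lives normal with mean 6.3 days and SD
10 h (so most tags fail during the sixth or seventh day), restarts Poisson
at 0.2/day with 5 s gaps. A restart gap shorter than the washout is
absorbed; a longer one splits the event, and restarts of the *bookkeeping*
tag are the mechanism by which off-shift contacts can leak past the
cleaning stage, as observed in the field.

## Cleaning decisions

* **"Vicinity of the bookkeeping tag"** is operationalised temporally: an
  event of tag T is deleted if it overlaps any interval in which T was in
  contact with the bookkeeping tag (in addition to deleting the
  bookkeeping tag's own events). The deletion is idempotent.
* **Study-window filtering** clips straddling events at the window bounds
  and recomputes their durations rather than dropping them whole.
* **Reconciliation** matches the two sides' recordings of one physical
  contact when their start times agree within 300 s (the insertion-window
  bound) and keeps, by default, the lexicographically first tag's times
  (`first_tag` — the single-source heuristic); `mean` and `max` policies
  are provided. Unmatched events are kept and flagged `one_sided` — they
  arise from partner restarts, battery death or full memory.

## Network conventions

* **Day binning** credits an event's whole duration to the day bin of its
  start time, matching the convention of sorting raw data into daily files
  by contact start date; `split_credit = TRUE` offers the proportional
  alternative for sensitivity analysis. Under the start-date rule total
  daily edge weight equals total reconciled event hours exactly.
* **Eigenvector centrality** is the principal eigenvector of the weighted
  adjacency matrix normalised to *unit Euclidean length*. This keeps all
  entries in [0, 1] without forcing any entry to 1 (max-entry scaling
  would always produce a 1, inconsistent with reported maxima around 0.7).
  Disconnected networks are handled per component (unit norm within each
  component, isolates 0) and flagged.
* **`"<0.00"` cells** in printed contact matrices are recorded contacts of
  negligible duration; the default parse keeps them as weight-0 edges (they
  count toward degree but not strength), with a `drop` policy available.
* **Mixing** is summarised as the ratio of mean within-group to mean
  between-group off-diagonal heat-map cells. Unstructured random weighted
  graphs on 50 nodes keep this ratio inside [0.8, 1.25] in ≈ 99% of draws
  (Monte-Carlo calibration with uniform weights at edge density 0.5), so
  ratios outside that band — and in particular a between-group mean of
  exactly 0, as in the three-pasture block scenario — flag non-homogeneous
  mixing.
* **Classification universe**: unordered horse–horse pairs only. Whether
  person and location tags should enter the comparison is genuinely
  ambiguous in survey-vs-tag studies (a complete survey network on
  horse-only pairs forces specificity 0, yet nonzero specificities are
  reported alongside "essentially complete" survey networks); restricting
  to horses and exposing the restriction as a parameter
  (`restrict_to_type`) makes the choice explicit instead of hiding it. The
  per-aisle (rather than whole-barn) barn class is the default for the same
  reason: whole-barn membership makes the survey network complete.
* Undefined classification ratios (0/0) are reported as `NA`, never 0.

## Numerical and degenerate-input choices

* Time is integer wall-clock seconds from deployment start; 1 s
  granularity everywhere, matching the 1 Hz sensing loop.
* Gap arithmetic: a bout ending at second *e* and one resuming at *s* are
  merged iff `s - e - 1 < 30` (silent seconds strictly fewer than the
  washout).
* An `END` detected in the same second as a new `BEGIN` is stored first so
  each per-pair record stream stays well formed.
* Empty streams, empty days, memberships with a single group, and graphs
  emptied by type restriction all either return well-typed empty objects
  or raise a descriptive error, as documented per function.

## Problem sizes in the shipped checks

The test-suite and the acceptance script work at the following scales,
chosen to exercise every code path at interactive run times: unit fixtures
of 2–9 tags over minutes to two days; the one-week 33-tag default scenario
(≈ 7 M pair-seconds per seed) for 50 seeds in the survey-classification
property; 200 randomised traces for the washout oracle; and 100
Monte-Carlo draws for the mixing calibration. A single full-week seed runs
in a few seconds on one core.

## Known limitations

* The simulator's bout processes are the simplest renewal models producing
  variable daily weights; real contact bout-length distributions are
  heavier-tailed.
* Fence-hook clustering records co-pasturing as continuous pairwise
  contact, overstating individual-level contact during turnout (a known
  property of the deployment protocol, not of the software).
* Spurious detections are drawn from a configured candidate list rather
  than a propagation model.
* The survey comparison is unweighted by design; it says nothing about
  contact duration or frequency.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
sc <- default_scenario()
stream <- simulate_proximity(sc, seed = 1)
params <- default_tag_params(scenario_tags(sc)$id, seed = 1)
logs <- emulate_tags(stream, params, seed = 1)
registry <- build_registry(params, scenario_tags(sc))
events <- clean_contacts(logs, registry, window = c(0, 7 * 86400))
nets <- aggregate_daily(events, nodes = registry, n_days = 7)
centrality(nets[[1]], restrict_to_type = "horse")
survey <- build_survey_network(survey_from_scenario(sc))
classify_networks(weekly_combined(nets, "horse"), survey)
```
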
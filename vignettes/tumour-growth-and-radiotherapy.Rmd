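---
title: "An individual-cell model of hypoxic tumour growth and fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-cell model of hypoxic tumour growth and fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumoursim)
```

`tumoursim` is a Monte Carlo simulator of head-and-neck squamous-cell
carcinoma growth and conventionally fractionated radiotherapy. Every
tumour cell is an individual object with a type, an oxygen tension, a
state and a cell-cycle schedule; the simulation is event-driven, ordered
by each cell's next division (or death) time. This vignette describes
the model, its assumptions, the parameters that matter, and the design
choices made where the underlying biology leaves the design open.

## The growth model

A tumour starts as a single well-oxygenated stem cell and grows by cell
division through the proliferative hierarchy of epithelial tissue:

* **S** — stem cells: clonogenic and immortal. At division, with
  probability `spercent` (default 3%) a stem divides *symmetrically*
  into two stem daughters; otherwise it divides asymmetrically into a
  stem plus either a transit cell or a basal differentiating cell
  (50/50 by default).
* **T** — transit-amplifying cells: divide symmetrically for a limited
  number of generations (default 5), then differentiate.
* **D1 / D2** — differentiating cells created in, and above, the basal
  layer; each divides once more down the chain.
* **D3** — fully differentiated cells: never divide, and are lost by
  shedding/necrosis with an exponential lifespan (mean
  `d3_lifespan_days`, default 3.2 days).

Differentiated-cell loss deserves a comment, because it is the one place
where this package makes explicit a mechanism that descriptions of this
model family usually leave implicit. In a hierarchy whose terminal compartment
is immortal, the steady-state composition is forced: the terminal pool
accumulates one generation's production divided by the per-generation
growth rate (~3%), which drives the differentiated fraction to ~97% and
the stem fraction to ~0.2% for *any* choice of branching ratios. The
reported behaviour of this tumour type — about 1% stem cells, about 85%
differentiated cells, and control of an oxic 10^8-cell tumour by 30 x 2 Gy
— is only reachable if terminally differentiated cells turn over. A
~3-day mean lifespan corresponds to a cell loss factor near 90%, the
textbook range for head-and-neck carcinoma, and reproduces both the
composition and the control dose. Setting `d3_lifespan_days = Inf`
recovers the immortal variant.

With the defaults, growth converges by ~10^5 cells to a stable
composition of roughly 1.2% S, 16% T, 17% D1+D2, 66% D3 — i.e. ~83%
"differentiated" — and an oxic volume doubling time of ~35 days
(`doubling_time()` fits log counts over the statistically stable window
above 10^4 cells).

### Cell-cycle timing

Each newborn cell draws an exponential G0 phase (mean `g0_mean_h`, 1 h)
followed by a truncated-normal cell-cycle time (35 +/- 6 h, minimum 8 h),
giving an effective inter-division time of ~36 h. With stem gain
`spercent` per division this yields the ~35-day oxic doubling time; the
pair (`cct_mean_h`, `g0_mean_h`) is the calibration most users should
not touch. The G0 mean is deliberately short: cells in G0 carry the
reduced non-cycling radiosensitivity during treatment, so a long G0
would shelter a material fraction of stem cells from each dose fraction
and inflate the dose needed to offset accelerated repopulation well
beyond clinically reported values.

Low oxygen slows cycling: cycle times are multiplied by
`1 + A exp(-pO2/s)` (defaults A = 1, s = 3 mmHg), so anoxic cells cycle
at half speed while cells above ~10 mmHg are essentially unaffected.

### Oxygenation

Every cell carries a scalar pO2 (mmHg). Oxic tumours draw pO2 uniformly
on 5–100 mmHg. Hypoxic tumours are modelled with one of two calibrated
histograms ("moderate" and "severe"), implemented as inverse-CDF
samplers anchored to the published cumulative fractions below 2, 5, 10
and 20 mmHg (moderate: 7.3/22.1/45.6/65.4%; severe: 9.4/33.2/54.5/69.6%)
— a monotone Hermite spline below 20 mmHg and the conditional tail of a
log-normal (fitted to the 10- and 20-mmHg quantiles, truncated at
100 mmHg) above. A single two-parameter log-normal cannot satisfy all
four anchors simultaneously, so the anchors themselves are treated as
the operative specification and are reproduced by construction.

Hypoxia switches on at 10^6 cells (the avascular limit): all cells then
receive fresh pO2 from the configured histogram. At each division one
daughter retains the mother's pO2 and the other draws afresh, which
preserves the population marginal. Cells allocated pO2 below 1 mmHg
become quiescent with probability 50%; quiescent cells die with a 4-day
half-life unless reoxygenated above 1 mmHg, at which point they re-enter
the cycle with a fresh schedule.

## The radiotherapy model

Treatment delivers `dose_per_fraction` (2 Gy) once daily, five days per
week, until no target cell survives. Each fraction assesses every living
cell independently; the kill probability is

> p(kill) = (1 − SF(d)) × L(pO2) × (0.5 if non-cycling)

where SF(d) = exp(−αd − βd²) is the linear-quadratic surviving fraction
(α = 0.3 Gy⁻¹, β = 0.03 Gy⁻², so SF(2 Gy) = 48.7%), and L is the oxygen
enhancement ratio OER(pO2) = (1 + 0.81x)/(1 + 0.324x), x = pO2/0.616,
normalised to 1 at 60 mmHg and clipped there, so hypoxic cells are
protected by up to a factor ~0.41 at anoxia. The OER enters as a
multiplicative lethality factor on (1 − SF), not as a dose-modifying
factor inside the exponent; for 2 Gy fractions the two readings differ
by less than the Monte Carlo noise, and the lethality-factor form is the
direct translation of a "probability of cell death" curve. Non-cycling
cells — D2, D3, G0-phase and hypoxia-quiescent — are half as sensitive.
Sublethal-damage repair between fractions is not modelled.

Proliferation continues between fractions and through weekends.
Three eradication endpoints are recorded: stem cells, basal cells
(S + T + D1), and every living cell.

### Reoxygenation (ROx)

Tumour shrinkage improves oxygenation. Four hours after each fraction
(configurable; 4 h vs 23 h makes no measurable difference for daily
fractionation), every cell receives k × 3 mmHg with k drawn from
Binomial(n, 1/n) truncated at 4 (n = living cell count), so the mean
gain is 3 mmHg per cell per fraction and the probability of five or more
increments (&lt;0.5%) is negligible and redrawn. 60% of the quiescent
pool is eligible per event; retrieved cells re-enter the cycle. The
increment size and retrieval percentage scale linearly with (1 − SF(d))
relative to the 2 Gy reference, leaving the defaults exact for the
conventional schedule.

### Accelerated repopulation (AR)

AR is modelled as a multiplicative boost (default ×10, capped at
probability 1) to the symmetrical stem-division probability from a
configurable onset week. Under the boost the stem compartment's
doubling time drops from ~35 days to ~4 days. When a free-growth run is
continued with the boost, the total population needs several effective
generations before its structure re-equilibrates to the larger stem
fraction, so post-boost doubling times are fitted over the later part of
the continuation window only.

### The extra-dose-per-fraction analysis

To quantify how much extra dose AR costs, the package compares, on the
same grown tumour, a conventional course without AR (the *isoeffect*
schedule, n_iso fractions) with boosted courses started at onset weeks
0–3. The m extra 2 Gy fractions the boosted course needs are converted
into the equivalent uniform dose escalation over the post-onset part of
the isoeffect schedule (n_ar = n_iso − 5w fractions) by equating
biologically effective doses (BED = nd(1 + d/(α/β)), α/β = 10 Gy):
`extra_dose_per_fraction(n_ar, m)` solves the quadratic
n_ar(2 + Δ)(1 + (2 + Δ)/10) = (n_ar + m) · 2 · 1.2.

Two estimator choices matter and are deliberate:

* **Endpoint.** The comparison uses the *stem-cell* eradication
  endpoint. Stem survival is the classical criterion for local failure,
  and with the stem endpoint both the baseline and the boosted course
  are limited by the same population, which makes m/n_ar — and hence Δ —
  essentially independent of the onset week, as reported clinically.
  The total-kill endpoint would add a multi-fraction clearance tail from
  the large differentiated compartment that is unrelated to
  repopulation and swamps m at late onsets.
* **Averaging.** m is integer-valued and, at desk scales, small;
  replicate runs are pooled by averaging m and n_ar per onset week
  *before* the nonlinear BED conversion. Replicates share one grown
  tumour and re-seed the RNG identically before every course (common
  random numbers), so baseline and boosted courses follow the same
  realisation until the boost first acts.

With the defaults this yields Δ ≈ 0.5–0.8 Gy per fraction for onset
weeks 0–2. At the scaled-down problem size used throughout
(10^7 cells; the isoeffect course is then ~4 weeks rather than 6), onset
week 3 falls into the final week of the course: n_ar is ~4 fractions,
and the stochastic extinction of the last few boosted stem cells —
which can double over a weekend — contributes a fixed 1–3 extra
fractions that no longer averages out, inflating and destabilising
Δ(week 3). This is a finite-size artefact of the scaled comparison, not
a property of the model at clinical size.

## Simulation sizes and numerical choices

* Default experiments grow tumours to 10^7 cells (composition is stable
  from ~10^5, doubling-time estimates from 10^4), treat at 10^7, and use
  9 replicates for the extra-dose analysis; a full 10^8-cell growth is
  supported and behaves identically per the scale-invariance checks in
  the test suite.
* The event queue is a calendar queue (1-hour buckets; the current
  bucket is sorted, rare intra-bucket insertions go to a side heap).
  Ties in event time are broken by insertion order. Cancelled events are
  invalidated lazily via per-cell sequence stamps.
* All randomness — uniform, exponential (inversion), normal (Box–Muller)
  — derives from R's generator, so `set.seed()` makes any run, growth
  or treatment, bit-reproducible. A single stream is used; toggling a
  feature therefore shifts downstream draws, which is why experiments
  re-seed per course rather than relying on stream independence.
* Truncated-normal cycle times are drawn by rejection (the truncation
  point is 4.5 SD below the mean, so rejections are rare).
* pO2 is clamped to [0, 100] mmHg everywhere; reoxygenation increments
  saturate at 100 mmHg.
* Degenerate inputs: growth with parameters that kill every lineage
  reports `"extinct"` rather than failing; a store holding only
  immortal non-cycling cells reports `"stalled"`; treatment that fails
  to control within `max_weeks` (default 20) reports non-control.

## What the synthetic populations do and do not emulate

Unit tests and experiments build populations with
`make_fixture_population()` (exact type/state/pO2 compositions with
schedulable division times) or by running the generator itself. These
emulate the *model's* study conditions — histogram-calibrated oxygen,
hierarchy proportions, fraction timing — not patient data: there is no
spatial structure (homogeneous dose, non-spatial oxygen allocation), no
vasculature or nutrient dynamics, no cell-cycle-phase-specific
radiosensitivity beyond the cycling/non-cycling split, no
sublethal-damage repair, and oxygenation histograms are stationary
inputs rather than emergent physiology. Passing tests demonstrate
internal consistency with the published calibration targets, not
predictive accuracy for individual tumours.

## Known limitations

* The exact branching ratios and transit generation count of the
  original epithelial hierarchy are not recoverable from the published
  description; the defaults here are calibrated to the stated
  composition targets and exposed in `growth_params()`.
* Quiescent cells retrieved mid-schedule are irradiated at the
  sensitivity of their state at the moment of each fraction.
* The severe-hypoxia distribution is calibrated to its histogram
  anchors but, as published, produces outcomes close to the moderate
  case.
* Endpoints at desk scales (10^6–10^7 cells) carry a few-fraction
  stochastic tail from last-cell extinction; replicate and average.
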
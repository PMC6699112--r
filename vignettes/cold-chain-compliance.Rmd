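---
title: "Auditing the intrahospital blood cold chain from RFID tag telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the intrahospital blood cold chain from RFID tag telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtrace)
```

## The audit model

A tagged red-cell concentrate leaves the blood transfusion laboratory (BTL),
moves through corridors and ward storage rooms, and ends its journey either
in a stop box (transfused) or back at the BTL (returned). Its active RFID
tag records temperature every 8 minutes and is seen by paired door readers
at each room transition. `coldtrace` treats that event stream as the sole
evidence and asks, per product, whether its management complied with four
guidelines: the 2–6 °C storage window, the 1-hour limit outside validated
cooling before transfusion, the 24-hour transfusion deadline after a >10 °C
breach, and the 24-hour return deadline for unused products.

Three modelling commitments shape everything downstream.

**Phases follow room function.** Products inside a storage room are assumed
to sit in its refrigerator, so BTL and storage rooms are *storage*,
corridors are *transport*, and — for transfused products — everything after
the final exit from a storage-capable room is *transfusion* (transfusion
data run from leaving storage to the stop-box drop). A stop box mounted
inside a storage room therefore makes storage and transfusion data
inseparable, and such records are excluded rather than guessed at.
Non-validated ward coolers are representable as storage rooms with
`has_validated_cooler = FALSE`: readings there still count as storage for
the temperature guideline, but time there counts against the 1-hour
out-of-cooling limit, which deliberately over- rather than under-estimates
guideline-2 violations.

**Recorded values are judged as recorded.** The tag sensor reads about
0.26 °C high and reports on a 0.5 °C grid, so the storage window is widened
by a 0.5 °C allowance to [1.5, 6.5] °C on recorded values, and a recorded
11 °C is the evidence threshold for the 10 °C breach limit. Readings within
the first hour after tag activation are discarded: tags are handled at room
temperature and need time to equilibrate, and early warm readings say
nothing about the product. Transfusion-phase readings are discarded too,
because products are deliberately warmed just before transfusion.

**Boundaries are compliant-inclusive.** Exactly 1.00 h outside cooling,
exactly 24.00 h to return, a recorded 6.5 °C — all comply. No source states
open or closed intervals; inclusive limits favour the product, and the
published compliant ranges (returns at 23.12–23.83 h) are consistent with
them.

## Dispositions and dataset selection

Each tag-activation episode becomes one trace whose disposition is derived
from its terminal evidence: a stop-box drop means *transfused*; a BTL
deactivation means *returned*; no event outside the BTL means *never left*;
a tag that fell silent away from the BTL is *lost*. One case is not covered
by those four rules: a trace that left the BTL and whose last observed event
is back at the BTL, but whose deactivation was never registered. We treat it
as *returned* with an absent return time — it stays in the cohort and
becomes *excluded for missing data* at classification, which is how
unregistered returns are accounted in practice.

Inclusion applies four reasons in precedence order: never-left, lost,
unseparable (stop box inside the ICU storage room), and finally "no usable
sub-dataset". The last needed an operational definition: a phase is usable
when it holds at least one reading and no within-segment gap exceeds the gap
limit (24 min, i.e. three missed 8-minute samples), and a product is
excluded only when *no* phase is usable. A naive "every phase gappy" rule
would be untriggerable, since corridor transits are shorter than the gap
limit and often contain no reading at all, making transport vacuously
complete.

Assessability is then per guideline: guideline 1 needs eligible readings and
a gap-free storage/transport series; guidelines 2 and 3 need cooling-exit
and transfusion timestamps; guideline 4 needs departure and return
timestamps. One plausibility rule stands in for manual curation: a stop-box
drop more than 24 h after cooling exit (tags pocketed by staff and dropped
days later) cannot be a real transfusion time, so guidelines 2 and 3 become
unassessable for that product. The 24-h cutoff is the only duration the
guidelines themselves license; real out-of-cooling intervals are on the
order of a few hours, late drops are days, so the rule is insensitive to the
exact value.

## The thermal-lag sensor model

The simulator drives each tag's temperature by first-order relaxation
toward the current room's ambient:

$$T(t + \Delta t) = T_{amb} + (T(t) - T_{amb})\,e^{-k \Delta t}.$$

Bench data summarise the sensor's lag as a *mean* cooling speed — 0.42 °C/min
over the first 30 minutes of a 23 → 5 °C transition — which a linear model
cannot extrapolate (it would cross the ambient). `calibrate_rate()` solves

$$\frac{(T_0 - T_{amb})(1 - e^{-k w})}{w} = 0.42\ \text{°C/min}, \quad w = 30\ \text{min}$$

by bisection to 1e-9, giving $k \approx 0.040\,\text{min}^{-1}$. The blood
product itself equilibrates more slowly than the tag; it is modelled with
$k_{product} = k_{tag}/3$, but only the tag temperature is observable, which
is exactly the observability gap a real deployment has. Recorded values add
the +0.26 °C bias and are quantized half-up to the 0.5 °C grid (every
published temperature sits on that grid).

```{r}
k <- calibrate_rate()
c(k = k, mean_slope = (23 - tag_temperature_step(23, 5, k, 30)) / 30)
```

## What the simulator emulates — and what it does not

`simulate_cohort()` samples each product's journey from six templates
(never-left; lost in transit; operating-room transfusion; ICU transfusion
with the stop box inside the storage room; operating-room and ICU returns),
with log-normal dwell times — always positive and right-skewed, matching
long return tails. Defaults encode the study conditions wherever those are
stated, and otherwise one fixed choice of what a hospital cohort plausibly
looks like:

* fate tallies 7 / 13 / 40 / 52 / 131 (+1 unusable record) out of 243, with
  the unreported OR/ICU split of the 131 returns set to 66/65;
* theatre dwell (= time outside validated cooling before transfusion) sized
  to a 3.74 h mean;
* return dwells modelled as a ~23.1 h base hold plus log-normal excess.
  A plain log-normal matching the 28.8 h (OR) and 46.2 h (ICU) group means
  would put roughly half the returns under 24 h, which is irreconcilable
  with compliant returns being rare and tightly bunched just under the
  limit (23.12–23.83 h); base-plus-excess reproduces both features;
* missingness rates from the observed completeness: 2% transmission
  dropout, 3/52 late stop-box drops (delay 4–6 days, pocket ambient 30 °C —
  body-adjacent, otherwise unreported), 12/130 unregistered returns;
* refrigerated rooms at 4 °C; corridors, theatres and bays at 22 °C; tags
  activated at 22 °C (ambients per room are config, not assertion).

The generator does *not* model radio propagation, reader collisions, battery
depletion, or tags mis-dropped into another room's stop box by default
(`wrong_box_p` exists but is off). Passing tests on simulated cohorts
therefore validates the *pipeline logic* — reconstruction, segmentation,
selection, rule arithmetic — not the fidelity of any particular hospital's
dwell-time or temperature distributions.

Ground truth is labelled at generation time by straight-line arithmetic on
the known journey times and the noiseless tag signal, independent of the
event-stream reconstruction path. The pipeline's central validity check is
exact recovery: on a noiseless cohort (bias, quantization, dropout and
misuse all zero) every included product's category and every per-guideline
verdict must equal ground truth. With noise on, recorded-vs-true divergence
is genuine sensor physics, not a bug: a tag crossing a warm corridor in
under one sampling interval can miss a true product excursion entirely.

## Numerical choices and degenerate inputs

* Timestamps are UTC POSIXct at one-second precision; temperatures are
  stored to 0.1 °C. Event CSVs round-trip losslessly at those precisions.
* Room-transition boundaries are gateway-anchored; a missed gateway falls
  back to the midpoint between the last event in the old room and the first
  in the new one. Zero-length segments from coincident boundaries are
  dropped; segmentation always tiles the observed interval exactly.
* A trace with no readings cannot be segmented and is excluded as having no
  usable sub-dataset. An empty eligible-reading set makes guideline 1
  unassessable rather than compliant.
* `percent_round()` rounds half-up to one decimal (banker's rounding would
  disagree with published count/percent pairs).
* Guideline 3's 24-hour window is anchored at the first recorded breach, as
  the guideline's own text reads; whether a published analysis measured it
  from BTL departure instead is ambiguous, so `g3_anchor = "departure"` is
  available as a config switch. Its "must not be restored" clause is
  evidence, not verdict: restored-after-breach products are still scored by
  the 24-hour transfusion window alone.
* Per-guideline denominators are always reported from the data at hand, not
  hard-coded; published sources themselves disagree by one or two products
  on the transfusion-dataset denominators.

## Problem sizes used in validation

The shipped checks run a 243-product cohort with the study tallies for the
selection arithmetic, a 500-product noiseless cohort for exact ground-truth
recovery, and four 260-product randomized cohorts (varying mixes, dropout up
to 25%, misuse up to 30%) for partition invariants — segmentation tiling,
single assignment of every reading, and category counts summing to the
cohort. These sizes give every journey type double-digit representation
while the whole suite stays interactive.

## Known limitations

* Location is room-granular and assumed to persist between gateway events;
  there is no indoor positioning within a room.
* The pipeline never imputes missing readings; incompleteness always flows
  to unassessability or exclusion instead.
* The unseparable-ICU rule keys on the drop room being storage-capable; a
  facility with stop boxes only in theatres will never trigger it.
* Bedside patient matching (mistransfusion checking) is out of scope: the
  tag infrastructure modelled here does not observe it.
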
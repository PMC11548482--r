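---
title: "Methods: glow-curve quality control in glowqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glow-curve quality control in glowqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowqc)
```

## Scope and model of the data

`glowqc` screens glow curves from LiF:Mg,Ti dosimeter cards read at a
25 °C/s heating profile. A curve is a vector of 200 non-negative channel
intensities in arbitrary photomultiplier-current units; the dosimetric glow
peak sits at channel 95. Channel indices are 1-based and all window bounds
are inclusive. A linear channel→temperature map with `T(ch) = 15 + 2·ch`
(so `T(95) = 205` °C) is provided for plotting only; no decision rule uses
temperature. Doses are carried in mrem (1 mrem = 0.01 mSv); the reporting
level is 20 mrem.

The pipeline is deliberately a hybrid: a trained shape filter removes the
bulk of unremarkable curves cheaply, and deterministic, auditable rules make
every classification that a technician might have to defend. All thresholds
live in one configuration object (`gc_config()`), so a laboratory can
re-tune the rules without touching code.

## Background reduction

The expected ambient dose accrued between the previous and current read is
linear in elapsed time, `Bgd = RadiationPerWeek · (day2 − day1)/7`, with
`RadiationPerWeek` defaulting to 1 mrem/week. Fractional weeks are kept as
real numbers. Any value below 1 mrem is floored to 1: this covers the
negative intervals that arise from swapped or mistyped read dates, the
same-day case, and sub-week wear periods with a single conservative rule.
Missing dates fall back to the same floor with a warning rather than an
error — a dosimeter with bad metadata should still flow through the
pipeline and surface in the statistics store. Subtraction floors each
element dose at zero (a negative physical dose is meaningless) and keeps the
raw doses on the record for audit.

## Reporting-level filter

Elements under their per-element thresholds (`Threshold1..Threshold3`,
`ThresholdNeut`; 1 mrem by default, i.e. effectively inactive until a lab
raises them) are zeroed first; the dosimeter is dropped from review when the
remaining total is at most 16 mrem, so that adding the typical background
back cannot lift it over the 20 mrem reporting level. Whether per-element
thresholds should zero elements or discard whole dosimeters was an open
design point; zeroing was chosen because it is the weaker intervention and
the zeroed indices are reported, so the stronger policy can be layered on
downstream.

## Shape filter

The filter is a feed-forward network with the fixed architecture
202–5–15–5–1: 200 max-normalized channels plus the kurtosis and skewness of
the curve viewed as a probability mass function over channel indices
(standardized 4th and 3rd central moments; kurtosis is reported raw, not as
excess). Max-normalization makes the features — and therefore the decision —
exactly invariant to intensity scaling, which is correct here because dose
magnitude is the business of the earlier filters.

Choices the architecture does not pin down were made as the smallest
standard ones: ReLU hidden activations, a logistic output trained with
class-weighted cross-entropy (the anomalous class is up-weighted by the
inverse class ratio), full-batch Adam at learning rate 0.01 for up to 400
epochs with early stopping (patience 60) on the validation loss, and
He-normal initialization from a fixed seed. Inputs are standardized with
training-split statistics and clipped at ±8 standard deviations, because
near-empty tail channels have tiny variances and would otherwise produce
unbounded activations exactly for the anomalies that matter. Training is
deterministic given the seed; persisting the same model twice yields
byte-identical JSON.

The labeled set is split 60/20/20 into train/validation/test, stratified by
class with the train count rounded down per class and the remainder halved
(1608 curves with 144 anomalous give 964/322/322). The decision threshold is
0.91 on the probability of being normal, compared strictly (`>`), so a
boundary curve goes to the rule cascade — consistent with the filter's
stated preference for false negatives (normal curves sent to review) over
false positives (anomalies passed as normal). With `bUseAI = FALSE`, or
when no model is supplied, every retained curve is forwarded as suspect.

## Integral-ratio plausibility

Two conditions on the element doses, checked in order. The spread condition
`(max − min)/max < Crystals_Quotient` (default 0.25) passes concordant
elements. Failing that, the four dose ratios `L4/L3, L3/L1, L3/L2, L1/L4`
are matched against 21 tabulated radiation fields; a row matches when every
computable ratio is within `ratio_table_threshold` of the row's value. The
tolerance is absolute (the parameter is documented as a 0–1 quantity); note
that at the default 0.05 several near-unity fields (e.g. the 48 keV and
118 keV qualities and Cs-137) are mutually indistinguishable — the filter
only needs *some* match, and `ratio_table_match()` returns both the first
matching row and the full match set. On 3-element cards the two
L4-involving ratios are skipped and a row matches on the remaining two. A
zero denominator makes a ratio `Inf`, which matches only a table value
larger than `1/tol` (the table's sentinel magnitudes such as 6200); `0/0`
ratios are skipped. A dosimeter passing neither condition goes to manual
review.

## The rule cascade

Class D is evaluated first, on the raw curve. The spike predicate at index
`i ∈ 1..197` requires a sharp rise into channel `i+1` and a sharp fall
within two channels (first condition AND (second OR third)), with
`SpikeNeighDiff = 50`% by default; adjacent firing indices are merged so a
single physical spike counts once. Strictly more than `NSpikes = 3` events
classifies the curve as D and ends the cascade — a spiky curve is never
smoothed or relabeled.

Below the budget, each spike is removed by replacing its 1–2 implicated
channels (channel `i+1`, plus `i+2` when only the two-channel condition
fired) with linear interpolation between the nearest untouched neighbours.
Interpolation was chosen over a global moving average precisely so that
every other channel is bit-identical, which keeps the window averages of
the later rules, and the tests over them, exact. The operation is
idempotent once spikes are removed.

Classes A, C, B, E follow, mutually exclusive, on the smoothed curve.
Class A requires the maximum inside 95 ± `MaxAllowedShift` (default 10) and
a window average strictly between `MinBgdHeight = 10`% and
`MaxBgdHeight = 50`% of the maximum over the low window (channels 1–40) or
high window (160–200); both sub-classes may hold at once. If the peak
precondition fails the curve falls to class C, which splits on the maximum
being above or below the allowed interval, with argmax ties broken to the
lowest channel. Class B then tests width: wide when the central window
(55–135) averages above `WideAvgVal = 60`% of the maximum, narrow when both
flanks beyond `half_width_num_ch = 25` channels of the peak average below
`NarrowAvgVal = 5`%; an empty flank window (peak within 25 channels of the
curve edge) is treated as vacuously satisfied. Class E is the residual.
Defaults for all window and percentage parameters were calibrated once
against the simulator's default preset — the normal preset classifies to
none of A/B/C/D, and each injected anomaly lands in its class with margin —
and are not adjusted thereafter.

## Correction

Only class A is corrected: the parasitic signal occupies a temperature end
the dosimetric peak does not, so channels `1..LowCutCh` (40) and/or
`HighCutCh..200` (160) are cut and the dose recomputed as
`dose_calibration × Σ channels`. The cut replaces with zero rather than an
extrapolated baseline: the goal is removing background dose, zero makes the
dose effect exactly auditable, and alternative baselines can be added
behind the same interface. Corrections therefore never increase dose. Under
`bFullAutomated` a proposal is applied without approval, except when the
pre-correction dose exceeds `ManualReviewThreshold` (500 mrem) — high doses
always get human eyes. The corrected integral is reported alongside the
original and does not re-enter the reporting-level decision.

`dose_calibration` defaults to 0.005 mrem per unit of integral, chosen so
the simulator's default curve (integral ≈ 3 × 10⁴ units) corresponds to a
realistic occupational dose of ≈ 150 mrem; real deployments would set it
from their reader calibration.

## The simulator

The simulator stands in for a private reader database, so its defaults are
the package's study conditions. Normal curves are sums of asymmetric
Gaussians — main peak at channel 95 (width 8, slight high-temperature
skew), satellites at 60 and 125 at a quarter of the main height — with
log-normal jitter (sd 0.1) on heights and widths (never on centers, so the
noiseless preset peaks exactly at 95), multiplicative Gaussian channel
noise with coefficient of variation 0.05, and a near-constant dark-current
pedestal at 0.2% of the maximum. The pedestal is modelled with small
*relative* variation deliberately: independent noise in empty tail channels
would produce large channel-to-channel ratios and spurious spike
detections that real dark current does not show. A first-order-kinetics
generator could replace the peak model behind the same interface; the
classifiers only consume channel statistics, so Gaussian morphology
suffices for them.

Anomaly injection is label-faithful by construction: pedestals of 30% of
the maximum over the class-A windows; the dominant peak widened 3× for
`B_WIDE` (satellites untouched — widening everything would bleed satellite
signal into the low-temperature window and alias into class A) versus all
widths compressed 4× for `B_NARROW`; whole-curve translation by 20 channels
for class C; five spikes of 3× the local amplitude, 1–2 channels wide and
at least 4 channels apart, for class D; and for class E a multiplicative
ripple (amplitude 0.5, period 30 channels) whose phase is resampled until
the cascade assigns exactly E — documented generate-and-filter, since E is
defined only negatively. The training mix uses an anomalous fraction of
144/1608 ≈ 9%, mirroring the imbalance such a filter faces operationally;
anomalous curves split equally across the eight labels unless a mix is
given, apportioned by largest remainder so counts are exact and
reproducible from the seed.

What passing tests on this simulator does and does not show: the rule
cascade's label recovery (100% for shift and spike classes, ≥95% for the
threshold-sensitive width and pedestal classes at the default magnitudes)
and the filter's held-out recall (≥0.95 at threshold 0.91) demonstrate
internal consistency of rules, thresholds and injected morphologies — not
performance on any laboratory's real distribution, whose anomaly magnitudes,
noise and drift the simulator does not claim to match. Deploying on real
data requires re-training the filter and re-examining the window defaults.

## Problem sizes and numerical points

The shipped suites use: 10,000 random curves for the spike-rule
brute-force equivalence, 1,000 random dose quadruples for the ratio-table
equivalence, 1,000 zero-noise curves (125 per class) for label
faithfulness, and the full 1,608-curve protocol for filter training —
sizes at which every property has run stably and the whole suite completes
in well under a minute on one core. Degenerate inputs are handled
explicitly: an all-zero curve is rejected by feature extraction (it should
never survive the dose filter), a zero maximum fails the spread check into
manual review, argmax ties break low, and a window average exactly on a
class-A bound is excluded by the strict inequalities.

## Statistics store

Persistence is an append-only CSV file with query helpers (date range,
reader, label) rather than a database server: it is transparent,
zero-dependency and sufficient for desk-scale batches, and the distribution
summary built on it counts the two class-A sub-labels separately (their sum
may exceed the number of classified dosimeters, since a curve can be both
`A_LOW` and `A_HIGH`). Dosimeter-level labels are taken from the
highest-priority anomalous element (spikes, then elevated background, then
shift, then width, then E); per-element details stay in the store.

## Known limitations

No glow-curve deconvolution into kinetic peaks, no heating-profile
distortion correction, no dose-response or fading model, and no corrections
for classes B, C, D, E (none is well-defined without operator judgment).
The ratio table's near-unity fields are not separable at the default
tolerance, which is immaterial for filtering but means the reported beam
name is a representative, not an identification.
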
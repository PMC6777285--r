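---
title: "Validating wearable heart-rate trackers with hrconcord: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable heart-rate trackers with hrconcord: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrconcord)
```

## The problem

Optical wrist trackers estimate heart rate (HR) from pulsatile
blood-volume changes under the skin. The estimate degrades with motion,
poor skin contact, and high heart rates, so tracker HR must be validated
against a criterion device — a chest strap whose HR agrees closely with
ECG — before it can support physical-activity research. A validation
study records criterion and tracker simultaneously in two settings: a
controlled laboratory exercise session spanning a wide, known HR range,
and an unconstrained free-living wear day. `hrconcord` implements the
statistical pipeline for such a study and a simulator for its designs.

## Epoch grid and matching

Devices sample at different rates (here 1 Hz for chest strap and
consumer tracker, 0.1 Hz for a low-cost tracker). All comparisons happen
on a canonical 10-second grid anchored at Unix-epoch-aligned boundaries
(timestamp seconds ≡ 0 mod 10). The default extraction rule takes, per
epoch, the instantaneous reading at the grid timestamp. We chose this
over a window mean because a 0.1 Hz device can only supply instantaneous
values, so the rule is uniform across devices; a `window_mean` option
exists for sensitivity checks. No lag search is performed: devices are
assumed NTP-synchronised, which modern study setups satisfy. An
integer-second clock offset would surface as inflated noise, not be
corrected.

Zero readings are how these devices report no-contact/dropout, so
matching keeps only epochs where **both** devices report a nonzero
value. Filtering the criterion's zeros too is our choice (a 0 bpm
criterion is nonphysiological and would break MAPE's division). Epochs
with no reading are absent, never zero-filled, which keeps "wear time" —
nonzero epochs × 10 s — well defined.

Participants enter a phase's analysis only with ≥ 60 matched laboratory
epochs (10 min) or ≥ 1,080 matched free-living epochs (180 min),
boundaries inclusive. A `complete_triplets` mode restricts to epochs
available from all three devices, the usual secondary analysis.

## Agreement statistics

All statistics pool matched epochs across participants, with differences
oriented tracker − criterion (underestimation is negative).

**ICC.** We use ICC(2,1) (= ICC(A,1)): two-way layout with epochs as
rows and the two devices as columns, single measures, *absolute
agreement*, so a systematic offset lowers the coefficient — which is the
question a validation study asks. From the balanced two-way mean
squares,

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}, \qquad k = 2,$$

with the F-based confidence interval (Satterthwaite degrees of freedom).
The mean squares are computed with the exact balanced-design identities
rather than an explicit epoch-factor regression, which would need an
n × n model matrix and is infeasible for pooled cohorts of 10⁴–10⁵
epochs. Pooling epochs ignores within-participant correlation, so the
CIs are narrow in exactly the way pooled-epoch validation reports are;
a per-participant reading of agreement is available by running
`agreement()` on per-participant subsets. Degenerate input (no variance
across epochs) returns 0 with a warning rather than an error, since a
pipeline must survive pathological streams. Qualitative bands: weak
< 0.50 ≤ moderate < 0.75 ≤ strong < 0.90 ≤ very strong, upper band
inclusive at each boundary.

**Errors.** MAE = mean|d| in bpm; MAPE = mean(|d|/criterion) × 100 with
a 10% validity cutoff (the convention endorsed for HR devices); mean
difference with normal-approximation CIs on the epoch-level mean.
Reported tables round half-up — ICC to 2 decimals, bpm and percent
quantities to 1, zone rates to 2 — matching the field's reporting
precision; returned objects keep full precision.

**Bland–Altman.** Limits of agreement mean(d) ± 1.96 SD(d) (sample SD),
with the per-pair (mean, difference) table emitted for plotting
(`plot_bland_altman()`).

**Outlier sensitivity.** Participants whose laboratory Pearson r between
tracker and criterion falls below 0.3 almost certainly had a mis-seated
device; `flag_outliers()` identifies them (participants with < 3
laboratory pairs are "not evaluable") and `agreement(...,
exclude_outliers = TRUE)` or the pipeline flag recomputes without them.

## Deciles and MVPA zones

`assign_deciles()` ranks matched epochs by criterion HR and splits them
into ten equal-count bins (sizes differ by at most one; ties break by
timestamp, making the split stable and reproducible). We use the rank
split, not value-based quantile cuts, because the scientific object is
"the lowest/highest 10% of epochs". Per-decile means of both devices and
of their difference expose HR-dependent bias: a tracker that reads
progressively low at high HR shows |mean difference| growing with decile
index.

Zone analysis classifies each epoch as MVPA when HR ≥ 64% of the
participant's age-predicted maximum, HRmax = 220 − age, boundary
inclusive (with a 10⁻⁹ bpm slack so thresholds like 0.64 × 190 = 121.6
compare exactly under floating point). Thresholds are per participant;
the 2×2 counts are pooled. Sensitivity = tp/(tp+fn), specificity =
tn/(tn+fp), accuracy = (tp+tn)/n, as percentages. Note that raising the
cutoff necessarily shrinks tp and tp+fp, but not fp alone — criterion
epochs reclassify too.

## The synthetic cohort

The generator emulates the two study settings so the full pipeline is
testable without proprietary exports.

**Truth trajectory.** A deterministic protocol backbone — piecewise
targets approached exponentially with time constant `tau` (default 30 s,
a realistic on-kinetics scale for moderate cycling) — plus a
mean-reverting Ornstein–Uhlenbeck wander (SD 1.5 bpm, correlation time
120 s). The wander keeps decile structure nontrivial; the backbone
guarantees laboratory stage means sit within the ±10 bpm protocol band
around 45/55/65/75% HRmax. Free-living days (default 12 h) run at a 45%
HRmax baseline with ≥ 1 MVPA bout (default one 10-min bout at 75%
HRmax, placed at random away from the day's edges, with a 60 s lead-in
so HR is above threshold for the declared bout). Truth is whole-bpm, as
real monitors report.

**Device error.** Each tracker reading is
`truth + additive_bias + proportional_bias · (truth − resting HR)` plus
Gaussian noise with SD `noise_sd_base + noise_sd_slope · (truth − rest)`,
floored at 0 bpm; with probability `dropout_prob` the reading is a
literal 0. Zeros, not missing rows, because the pipeline's
nonzero-filtering rule needs zeros to exist to be exercised. The stock
cohort models — a faithful criterion (2% dropout), a 1 Hz consumer
tracker (−1 bpm additive, −0.04 proportional, noise 2 + 0.02·excess,
2% dropout), and a 0.1 Hz low-cost tracker (−2 bpm, −0.08, noise
3 + 0.04·excess, 3% dropout) — encode the phenomenology validation
studies report: underestimation that grows with HR, more so for the
cheaper device, with heteroscedastic noise. Ages are uniform on 21–50,
resting HR ≈ N(62, 7²) clipped to [45, 80].

**What the simulator does not capture.** It is phenomenological, not a
model of optics or motion: no accelerometer-coupled artifacts, no
activity-specific error (cycling vs typing), no nonwear separate from
dropout, and a single error regime per device rather than
setting-dependent bias (real trackers can underestimate in the lab yet
overestimate in free living). Passing tests therefore demonstrate that
the *statistics* are computed correctly and recover known injected
structure — not that any particular commercial tracker is accurate.

## Numerical choices and degenerate inputs

- Seeds: every stochastic element takes an explicit seed; one master
  seed drives per-participant/phase/device sub-seeds, so cohorts are
  byte-identical across regenerations.
- SSE is obtained by subtraction from the total sum of squares and
  clamped at 0 against cancellation; the exact-agreement case (MSE = 0)
  returns ICC = 1 with a degenerate CI of (1, 1).
- Half-up rounding (`round_half_up()`) is used for all reported rates,
  since banker's rounding changes printed percentages at ties.
- Empty matches (disjoint grids) are valid empty results; inclusion then
  excludes the participant with a machine-readable reason rather than
  erroring.
- Pipeline runs in this vignette's scale and in the test suite use
  2–12 participants and shortened free-living wear where full 12-h days
  add nothing statistically; the statistics are invariant to that scale
  and the defaults remain the full study design.

## Limitations

Pooled-epoch CIs understate uncertainty relative to mixed-model
intervals with participant random effects (a deliberate trade for
comparability with standard validation reports); Lin's concordance and
regression-based bias correction are out of scope; bout-level MVPA
detection (10-min bouts rather than epoch counts) is not implemented —
the zone analysis counts epochs.
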
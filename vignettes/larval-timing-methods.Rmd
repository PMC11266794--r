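---
title: "Methods: quantifying larval developmental timing with larvadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying larval developmental timing with larvadev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvadev)
```

larvadev quantifies developmental timing in *C. elegans* larvae from four
kinds of input: a post-embryonic cell-lineage diagram image, per-individual
locomotor activity traces, binary pharyngeal-pumping rasters scored around
the L3-to-L4 transition, and length/width morphometry tables. Each analysis
stage is paired with a seeded simulator that produces ground-truthed inputs,
so every stage can be validated end to end without external data. This
vignette explains the models and procedures, the parameters that matter, the
numerical choices, and what the simulators do and do not emulate.

## Division density from a lineage diagram

A post-embryonic lineage diagram encodes division timing graphically: the
vertical axis is developmental time, vertical lines (2 px wide) are cell
lifetimes, horizontal bars (wider than 2 px, 2 px tall) are division events,
and cell deaths are marked by an 'X' built from five elements each at most
2 px across. `lineage_density()` turns such an image into a division-density
curve in four steps.

**Binarization.** Pixels at or below an intensity threshold become ink.
The default threshold is automatic (Otsu's method on a 256-bin histogram),
with a manual override; black-on-white line art is effectively binary, so the
threshold is uncritical.

**Narrow-element deletion.** `strip_narrow_elements()` scans the image row
by row and deletes every within-row run of ink at most 2 px wide. In every
row, vertical lines and 'X' strokes produce runs of width at most 2, whereas
division bars produce wider runs, so only the bars survive. We deliberately
chose this within-row run rule over connected-component deletion as the
default: in a real diagram the vertical lines *touch* the bars they
originate from (and the five strokes of an 'X' touch each other), so any
component-based rule would see one large component and delete nothing. A
component mode (8-connected, bounding-box width threshold) is still
available for diagrams whose elements never touch.

**Bar counting.** `count_bars_per_row()` counts maximal horizontal runs of
ink per row — the number of division bars crossing that row. Connectivity is
within-row only, so a 2 px-tall bar is counted in both of its rows; paired
adjacent peak rows in the output are expected and are not deduplicated.
Row coordinates are 0-based throughout.

**Time calibration.** Two anchor rows with known developmental times define
a linear row-to-hour map (`calibrate_time()`). The canonical anchors are the
two seam-cell division peaks shortly after the L2 and L3 onsets, at about 16
and 25 h post hatching; with anchors (448.5, 16 h) and (684.5, 25 h) the
slope is 9/236 h/px and the bottom of a 1034-row diagram maps to about
38.33 h.

**Inverse-kernel smoothing.** Raw counts are sparse spikes; `smooth_density()`
spreads them with an inverse-distance kernel
$k_j = 1/|j|$ for offsets $j \neq 0$ and $k_0 = 1$, over a window of
half-width $w$ (default 10 rows, exponent configurable). Each row's count
distributes its kernel mass over its window with the weights normalized *at
the source row* over the offsets that remain inside the series. This
"scatter" convention is our boundary rule of choice because it conserves
mass exactly — the summed density always equals the summed counts, which
keeps the curve interpretable as events per row. (Normalizing at the
destination row instead does not conserve mass near the edges.) Away from
the boundary the two conventions coincide, and a constant count vector is
reproduced exactly at rows more than $2w$ from either edge.

## Percent-of-stage activity profiles

Individuals traverse the same larval stage at different speeds, so averaging
activity traces on the wall-clock axis blurs stage structure. The profile
module instead maps each individual onto percent of stage completion:
for stage $j$ with duration $D_j$, the profile point at completion
percentage $i$ is the activity curve evaluated at $t = D_j \, i / 100$,
by linear interpolation between the neighbouring samples (endpoints take the
nearest sample). The default grid step is 1% ($i = 0, 1, \dots, 100$); with
traces sampled every 10 s and stages lasting hours there are many more
samples than grid points, so linear interpolation is essentially exact and
the choice of interpolant is immaterial. Population profiles are pointwise
means with SD and SEM (`average_profiles()`); the per-point $n$ is tracked
so missing individuals reduce the denominator rather than biasing the mean.

Stage boundaries are *inputs* — the package does not infer molts from raw
locomotion. `suggest_boundary()` offers an activity-minimum heuristic for
exploration, but it is explicitly not part of the analysis path.

The simulator (`simulate_activity_cohort()`) draws per-individual durations
from a normal distribution (default mean 8 h, CV 0.15 — a typical mid-larval
stage), evaluates a shared template of percent completion, and adds white
Gaussian noise (default SD 0.1 in activity units at a 10-s sampling
interval). Real locomotion data have temporally correlated, state-dependent
(roaming/dwelling) fluctuations rather than white noise; passing the
template-recovery tests therefore demonstrates correctness of the cropping,
resampling and averaging arithmetic, not robustness to behavioural state
structure.

## Lethargus and feeding metrics from pumping rasters

Pharyngeal pumping ceases during lethargus, so brief pumping observations on
a fixed grid (default: 10-s observations every 20 min between 32 and 39 h
post hatching) localize the L3-to-L4 quiescent period. `call_lethargus()`
scores one animal's row: entry is the first observation without pumping,
quiescent bouts are maximal runs of non-pumping observations before L4 onset
(the first observation with pumping and an invaginated vulva, when that
annotation is present; otherwise the end of the window), total duration is
the number of quiescent observations times the interval, and the call is
fragmented when pumping resumed between quiescent bouts. Two conventions are
worth making explicit:

- **Durations are interval-censored.** Observations are snapshots; true bout
  boundaries are unknown to within one interval. Durations are reported as
  (count of quiescent observations) × interval, exactly, with no smoothing
  between observations; recovery against simulated ground truth is accurate
  to one interval by construction.
- **Fragmented episodes sum all bouts** by default, since the quiescence
  "preceding L4" is naturally the total; `longest_bout_only = TRUE` gives
  the per-longest-bout variant for sensitivity analyses.

Animals with no quiescent observation, or no L4 onset inside the window, are
returned as censored calls, never dropped: they still count in the
denominators of `stage_transition_fractions()` (fractions past L3 exit / L4
entry at a time point), but are excluded from duration summaries.
`feeding_fraction()` pools pumping observations across animals in a window
(observations, not animals, are the unit), and `feeding_fraction_compare()`
reports the between-group difference both as a ratio minus one and in
percentage points, because a reported "x% greater" can be read either way.
The long-episode threshold is 100 min (strictly greater). Group comparisons
default to Welch's t-test for continuous quantities and Fisher's exact test
for binary ones.

The raster simulator draws onset from a normal distribution centred at 34 h
(SD 0.75 h), so about half the cohort has exited L3 by 34 h, and duration
from a two-component normal mixture — a short mode (70 ± 15 min) and a long
mode (130 ± 20 min) with 20% weight — giving a realistic tail of episodes
above 100 min; lethargus episodes typically last 1–2 h. A fragmented animal
(probability 0.15) has one interior quiescent observation flipped back to
pumping, which guarantees the flag is exactly recoverable from the row. Note
that onset at 34 h plus these durations implies roughly three quarters of
animals entering L4 by 36 h; a cohort in which only half have entered L4 by
36 h would need systematically longer quiescence (median near 2 h), which
would contradict the short-mode-dominated duration distribution. The
defaults favour the onset and duration conditions; the implied L4-entry
fraction is whatever they produce. No distributional forms are estimated
from data — simulator parameters are explicit knobs, and every analysis is
validated against the simulator's recorded ground truth, not against
distributional assumptions.

## Morphometrics

Body volume is estimated from a cylindrical model,
$V = \pi L (W/2)^2$, with length $L$ along the skeletonized midline and
width $W$ at the vulva or ~2/3 of body length (the measurement location is
metadata, not enforced). `polyline_length()` sums segment lengths of a
hand-traced midline. Two timecourse analyses build on the volume:

- **Isomorphy** (`isomorphy_test()`): growth preserving proportions means
  the width/length ratio does not differ between groups at any shared time
  point. Ratios are compared per time point (Welch), Holm-adjusted across
  time points, and the verdict is isomorphic when nothing survives
  adjustment. The Holm adjustment keeps the family-wise false-alarm rate at
  alpha over the whole timecourse.
- **Divergence onset** (`divergence_onset()`): "the groups became
  different at time t" is operationalized as the earliest time point whose
  volume difference is significant (Welch, Holm-adjusted) *and stays
  significant at every later measured time*. The sustained-significance rule
  protects against one-off blips setting a spuriously early onset; both the
  rule's alpha and the test are configurable. When no sustained divergence
  exists the result is an explicit null, not an error.

The growth simulator uses exponential length growth
$L(t) = 250 e^{0.031 t}$ µm with width a fixed fraction (0.08) of length —
roughly a 100-fold volume increase over 50 h of larval growth — and 5%
multiplicative measurement noise. A second group follows the same trajectory
advanced by a configurable offset (default scenario: 2 h), either globally
or only from a divergence time onward; an `allometry_ratio_factor` breaks
isomorphy deliberately for power checks. Real larval growth is not exactly
exponential and its noise is not i.i.d.; the simulator is a test harness for
the estimators, not a growth model.

## Problem sizes and reproducibility

Validation cohorts mirror the scale of the underlying experiments: 200
animals for raster recovery, 50 traces for profile recovery, 30 animals per
group per time point over an 11-point timecourse for divergence detection
(100 seeded replicates for the replicate-rate checks), 100 random diagrams
for the renderer/parser round trip, and 1000 random vectors for kernel mass
conservation. All simulators are bit-reproducible under a fixed seed, and
`run_pipeline()` writes a JSON run log (package version, parameters, seed,
input MD5 hashes) next to every output so artifacts are traceable to their
configuration.

## Known limitations

- The diagram parser assumes the stated pixel dialect (2 px lines, >2 px
  bars). Anti-aliased or rescaled images must be binarized carefully; the
  deletion threshold is configurable but the dialect is not inferred.
- The exact inverse-kernel weight normalization in prior use of this
  diagram-processing approach is not fully documented; the kernel here is
  the stated inverse-distance form with a mass-conserving boundary rule, and
  both the half-width and the exponent are exposed rather than fixed.
- Lethargus metrics inherit the 20-min sampling resolution; episodes shorter
  than one interval can be missed entirely, and a fragmentation bout falling
  between observations is invisible by construction.
- Stage-boundary inference and automated worm segmentation are out of scope;
  boundaries and length/width values arrive as annotations.
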
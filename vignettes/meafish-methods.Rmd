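---
title: "Methods: MEA and locomotor seizure metrics for larval zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA and locomotor seizure metrics for larval zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meafish)
```

## What the package computes

meafish re-implements, as tested and reusable code, the analysis chain used
to characterize seizure-like hyperactivity in larval zebrafish: extracellular
voltage traces from a 64-channel (8 x 8) microelectrode array sampled at
12.5 kHz are band-pass filtered and thresholded into spike trains; spike
trains are summarized into the standard neural metrics (active electrodes,
weighted mean firing rate, bursts, network bursts); centroid swim
trajectories at 30 frames/s are summarized into locomotor metrics (distance,
velocity, rotation events, mobility, 2-min dark/light bins); and per-subject
metrics are compared across groups with the heteroscedasticity-robust
statistics standard in this literature. A synthetic-data generator with full
ground truth stands in for raw recordings, which are not publicly deposited
for this preparation, so that every stage is verifiable by parameter
recovery.

## Signal processing

**Filter.** The spike band is 200 Hz to 3 kHz. Only the cut-offs are
conventionally reported for this hardware, not the family or order, so the
package realizes the filter as a Butterworth band-pass of total order 4
applied forward and backward. The zero-phase double pass leaves spike times
unshifted and squares the magnitude response; the passband gain at 1 kHz is
about 0.996 and a 50 Hz tone is attenuated below 0.5%. The IIR recursion
runs in compiled code; the first and last 100 ms of each filtered trace are
excluded from detection so start-up transients can never masquerade as
spikes.

**Threshold.** The detector is set at 5.5 times the background-noise RMS,
applied to both polarities ("+/- 5.5"). The phrase "5.5 standard deviations
of the RMS of the background noise" is read the way MEA vendors implement
it: threshold = 5.5 x (robust noise RMS). The robust estimator is the median
absolute deviation about zero scaled for a Gaussian, `median(|x|)/0.6745`,
so spikes present during calibration barely inflate the threshold; the plain
RMS is available via `detector_spec(rms_method = "rms")`. Calibration is
fixed per recording: whether the original acquisition system tracked a
rolling RMS is not documented, and a fixed calibration is the reproducible
default. An externally calibrated RMS can be injected through
`detect_spikes(noise_rms = )`, which is also how the threshold-recovery
sweep is run.

**Events.** An event is a contiguous excursion beyond the threshold; its
time is the extreme sample and its amplitude the signed extreme. Events
closer than a 2 ms dead time merge, keeping the larger excursion (ties keep
the earlier event). At 5.5 sigma the two-sided Gaussian exceedance predicts
far below 0.1 false events/min/electrode; the test suite asserts the
conservative bound of 1/min on pure-noise simulations.

## Neural metrics

All rule parameters follow the printed conventions for this preparation and
are held in `metric_spec()`:

- **Active electrode**: rate >= 5 spikes/min, *inclusive* - exactly 5
  spikes in 60 s qualifies, matching the vendor convention that "threshold
  of 5" admits 5.
- **Burst**: >= 5 consecutive spikes on one active electrode with every ISI
  strictly below 100 ms ("less than" is honored as a strict comparison, with
  a 1 ns floating-point tie tolerance so arithmetic on millisecond grids
  cannot flip the boundary).
- **Network burst**: >= 5 consecutive spikes on the pooled timeline with
  pooled ISIs strictly below 100 ms, involvement >= 10% of the electrodes
  (inclusive), and at least 2 distinct electrodes - "across multiple
  electrodes" excludes single-electrode runs even where the fraction rule
  alone would pass. The involvement denominator is all electrodes in the
  well (64); `denominator = "active"` switches to active electrodes only.
- **Analysis window**: the contiguous 5-min window maximizing total spike
  count, scanned on a 1-s lattice (exhaustive and cheap), ties to the
  earliest start. Metrics are computed inside this window, consistent with
  analyzing the 5 minutes of recording showing active neural responses.
- **Weighted mean firing rate**: the arithmetic mean of active electrodes'
  rates. With no active electrode the WMFR is `NA`, never 0 - complete
  silence is not a measured rate of zero.

**Brain-region hyperactivity.** Counting larvae with "hyperactive neural
activity in the brain region" has no published quantitative rule. The
package's own convention, exposed and documented as such: a larva is called
hyperactive when the WMFR of the head-mask electrodes is at least
`head_ratio_threshold` (default 2.0) times the WMFR of the remaining
electrodes; the supporting ratio is always returned, and the call is `NA`
(indeterminate, distinct from "no") when either region has no active
electrode. The default head mask is the 16 electrodes of the first two grid
columns, matching a laterally mounted larva whose head overlies one edge of
the array; real mounting varies, so the mask is a parameter everywhere.

## Locomotor metrics

Distance is the summed Euclidean displacement of the centroid track;
velocity is distance over elapsed time. Mobility compares per-frame speed to
a 0.5 mm/s threshold - a package convention, since the acquisition
software's pixel-change "mobility" is not reproducible from centroid
coordinates - and mobile plus immobile time always tile the analyzed span.

**Rotations.** The published definition gives two parameters, "a threshold
of 45 degrees and a minimum distance of 1 mm". Following tracking-software
convention, one rotation event is a full 360 degrees of cumulative
same-direction turning; 45 degrees is the opposing-turn tolerance (a larger
counter-turn resets the accumulator without counting) and 1 mm is the
displacement filter (headings are only updated between points at least 1 mm
apart). The alternative reading - every 45-degree turn is an event - is
available by setting `rotation_spec(full_turn_deg = 45)`. One discretization
property is worth knowing: on a circular path the chord polygon induced by
the 1-mm filter accumulates 360 degrees minus roughly one chord angle per
revolution (about 24 degrees on a 16-mm circle), so a path must close its
first revolution - not merely touch its starting point - before the first
event is counted. Counts are invariant under rotation and translation of
the coordinate frame, mirroring swaps CW and CCW, and counts agree across
30 and 60 frames/s sampling of the same smooth path.

**Phase bins.** The dark-to-light protocol is 5 min of dark acclimation
followed by a 12-min recording in 2-min dark/light cycles. `bin_by_phase()`
cuts the analyzed span into 120-s bins, labels each with its phase, and
computes every metric per bin; bin distances sum to the total. The phase
schedule is data (carried by the trajectory file), never inferred from the
signal.

## Group statistics

The statistical layer mirrors the field's standard battery: Welch's
unpaired two-tailed t (via `stats::t.test`), Welch's heteroscedastic
one-way ANOVA (via `stats::oneway.test`), the Brown-Forsythe F* one-way
ANOVA (implemented from its published formula - the ANOVA variant, not the
Levene-type spread test), two-way ANOVA with Tukey HSD across factor cells
(`stats::aov` + `stats::TukeyHSD`, which applies Tukey-Kramer for unbalanced
cells), and a repeated-measures one-way ANOVA for paired pre/post designs,
computed from the within-subject decomposition (for two conditions F equals
the squared paired t, which the tests assert). All p values are reported
raw; nothing is silently thresholded.

**ROUT.** The ROUT outlier procedure is specified against robust nonlinear
regression in its source publication; group comparisons here fit only a
location, so the package uses the constant-model specialization: the robust
fit is the sample median, the robust scale is the RSDR (68.27th percentile
of absolute residuals scaled by N/(N-1)), each point receives a two-tailed
t p value from |residual|/RSDR with N-1 degrees of freedom, and points are
flagged by Benjamini-Hochberg at FDR level Q (default 1%). Outlier removal
is an explicit, logged, opt-in step: `rout_outliers()` only partitions the
data, and which figures of any given analysis used it is an analyst
decision.

## The synthetic-data generator

No raw data are deposited for this preparation and the figures print no
numeric axes values, so the generator's defaults are order-of-magnitude
choices a practitioner would call realistic for 120-hpf larvae, fixed once
and documented here - not calibrated to any published figure:

- background noise: white Gaussian at 3 uV RMS (noise is never
  characterized in print; an optional 1/f admixture sits behind
  `pink_noise_fraction`, default off);
- spikes: biphasic 1-ms templates (one full sine cycle, exactly zero-mean,
  trough scaled to the target amplitude) at 10 x noise RMS, added linearly
  on top of the noise; overlapping spikes superpose;
- tonic firing: gamma(2)-renewal ISIs with a 2-ms absolute refractory
  period (prevents degenerate zero ISIs; physiological refractoriness), at
  1 spike/s/electrode;
- bursts: Poisson episodes at 4/min/electrode, 5 spikes at 50-ms ISI;
- network events: 2/min, recruiting `ceiling(involvement_fraction x 64)`
  electrodes with onsets jittered within 10 ms, so pooled ISIs sit far
  below the 100-ms criterion;
- episode separation: successive episodes on an electrode (and successive
  network events globally) keep a >= 1-s quiet gap
  (`episode_min_gap_s`), and tonic spikes are excluded from episode
  windows, so ground-truth episodes own exactly their own spikes and
  burst-count recovery can be asserted exactly;
- scenarios: `napb_cr` multiplies head-mask electrode rates by 2.5;
  `*_ptz` scenarios multiply all event rates by 2 and default to the
  30-min duration of the PTZ protocol (15 mM).

Trajectories are a correlated random walk in a 7.8-mm-radius well (24-well
format): gamma-distributed per-frame speeds (mean 3 mm/s control, 6 mm/s
mutant; CV 0.6), wrapped-normal heading increments (SD 25 degrees), brief
immobile pauses, sustained circling bouts entered at 0.02/s (control) or
0.15/s (mutant) that each complete one full rotation, and a wall-affinity
steering term (0.8 control, 0.2 mutant) that reproduces organized
wall-following in controls versus irregular interior swimming in mutants.
Wall handling is specular reflection with a final clamp, so containment
(`sqrt(x^2+y^2) <= arena_radius`) holds for every emitted point. PTZ
scenarios multiply speed by a factor decaying exponentially with a 300-s
half-life, emulating the waning drug effect. Ground truth (path length,
mean speed, rotation-bout count, mobile fraction) is computed from the
emitted positions, so downstream metrics can be checked for exact recovery.

What the generator does *not* emulate - and hence what passing tests do not
show about real data: agarose-contact and movement artifacts, volume
conduction and electrode crosstalk, spike-amplitude variability and
bursting structure beyond the renewal/episode model, non-stationary noise,
tracking dropouts, and body-orientation information (headings come from
displacements only).

## Numerical choices and degenerate inputs

- Strict ISI comparisons carry a 1e-9 s tie tolerance (five orders of
  magnitude below one sample at 12.5 kHz) so millisecond grids built by
  multiplication cannot flip a boundary either way.
- Window-selection ties break to the earliest start; event-merge ties keep
  the earlier event.
- Zero-variance groups, silent electrodes, empty spike sets, sub-3-point
  trajectories and zero-RMS channels all return defined values or typed
  errors rather than NaNs: see `weighted_mean_firing_rate()` (NA, with a
  warning), `classify_brain_hyperactivity()` (indeterminate status),
  `detect_spikes()` (flagged channels), `count_rotations()` ((0, 0) with a
  warning).
- Determinism: both simulators restore the caller's RNG state and produce
  bit-identical output for identical (configuration, seed).

## Problem sizes used by the test suite

The suites assert parameter recovery at the sizes the protocol describes
where that is cheap (a full 64-electrode, 5-minute recording for firing-rate
recovery), and scale down where a smaller size tests the identical code
path: burst-count recovery uses 60-s recordings, the involvement flip 120-s
recordings, the false-positive bound an 8-electrode 10-min noise recording,
and behavioral group recovery 4-min dark trajectories with n = 20 seeds per
group (50 seeds for the PTZ decay check). These sizes are the package's own
verification choices; the metrics themselves are size-agnostic.

## Known limitations

- Electrode-level analysis only: no spike sorting, no unit assignment, no
  LFP/oscillation analysis, and no synchrony measures beyond the network
  bursts defined above.
- The brain-region hyperactivity call is a package convention (ratio >= 2);
  treat counts built on it as convention-dependent.
- EthoVision's exact rotation algorithm is not public; both supported
  readings of the 45-degree threshold are exposed, but neither is guaranteed
  to match the vendor's implementation sample-for-sample.
- The recording container is the package's own flat-binary + JSON format;
  vendor acquisition formats need external conversion.
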
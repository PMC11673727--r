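---
title: "Integral-based assistance analysis of paired exoskeleton EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integral-based assistance analysis of paired exoskeleton EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibaemg)
```

## The problem

A back-support exoskeleton exchanges force and energy with its wearer. When
the timing and magnitude of that exchange are right, the wearer's muscles —
here the erector spinae, biceps femoris, and rectus femoris monitored in
lifting and bent-posture tasks — produce less activity; when they are
wrong, the device resists the movement and activity increases. Surface EMG
is the most direct practical window on this exchange: the same task is
recorded without the device (NoExo) and with it (Exo), and the two
activation envelopes are compared.

The conventional comparison reduces each condition to one characteristic
value of its amplitude distribution (mean, max, a percentile) and reports
the percentage variation

$$\mathrm{PV} = 100\,\frac{\mathrm{VAL}_{NoExo} - \mathrm{VAL}_{Exo}}
{\mathrm{VAL}_{NoExo}}.$$

This throws away the time course: a device that assists strongly while the
trunk flexes but fights the wearer while rising can still show a flattering
overall PV. The analysis implemented here keeps the sample dimension and
only then aggregates.

## The interaction trend and its indices

After the two envelopes are aligned sample-by-sample (section on
segmentation below), the interaction trend over an analysis segment is

$$I_{\mathrm{Trend}}(i) = 100\;
\frac{E_{NoExo}(i) - E_{Exo}(i)}{\sum_{j} E_{NoExo}(j)},$$

with the sum over the same segment. Formally the difference of the two
integrated EMGs (iEMG, the time integral of the activation envelope,
proportional to the neural energy spent) normalized by the baseline iEMG;
the sampling interval multiplies numerator and denominator alike and
cancels, which is why the implementation works with plain sums. Each sample
is the percent share of the segment's baseline neural energy that the
device adds or removes at that instant.

Three indices summarize a segment:

* **AII** (assistive): sum of the samples with $I_{\mathrm{Trend}} \ge 0$;
* **RII** (resistive): magnitude of the sum of the negative samples;
* **OII** (overall): $\mathrm{AII} - \mathrm{RII}$.

For a uniformly sampled segment, algebra gives
$\mathrm{OII} = 100\,(\bar E_{NoExo} - \bar E_{Exo})/\bar E_{NoExo}$ —
exactly the mean-based PV. The package treats this identity as a structural
invariant: `analyze_pair()` always emits `mean_pv` beside `oii`, and the
test suite checks their agreement to 1e-9 relative on thousands of
randomized pairs. What the decomposition adds over the mean is the
separation of assistive and resistive epochs and, through the trend signal
itself, *when* they occur.

Two normalization scopes exist. At `full_task` scope the denominator spans
the whole recording; at `per_phase` scope it is restricted to the phase
under analysis, so phase indices are percentages of the energy *that phase*
requires. Per-phase OIIs therefore do not sum to the full-task OII; they
relate through the phases' shares of the full-task baseline energy (a
weighted-sum identity the tests verify). Per-phase normalization is the
package default for phase tables because it makes a 40 % assistance during
a low-effort hold mean what it says.

Decisions fixed for determinism: samples with $I_{\mathrm{Trend}} = 0$
belong to the assistive partition (they contribute nothing numerically);
summation runs in ascending sample order, so `oii == aii - rii` holds bit
for bit; group statistics are computed per subject first and averaged
afterwards, preserving the OII/mean-PV identity within each subject.

## Preprocessing

Raw EMG becomes an activation envelope through the standard offline chain,
each step a separate exported function and the composition available as
`process_emg()`:

| step | default | why |
|---|---|---|
| band-pass | Butterworth order 4, 30–400 Hz | removes motion artifact and drift below 30 Hz, out-of-band noise above 400 Hz |
| rectification | full-wave | activation magnitude |
| low-pass | Butterworth order 4, 2.5 Hz | the slowly varying envelope |
| MVC reference | 95th percentile | robust "100 %" from the processed maximum-voluntary-contraction trial |

All filtering is zero-phase (forward–backward): the indices subtract the two
conditions sample-by-sample, so any group delay would masquerade as
assistance or resistance. The stated orders are design orders per pass.
Numerical choices that matter:

* Filters run as cascaded second-order sections. The direct
  transfer-function form of a 2.5 Hz low-pass at 1 kHz amplifies rounding
  by roughly $(1-\text{pole radius})^{-4} \approx 10^8$; sections keep the
  chain accurate to ~1e-12, which is what makes the measured invariances
  (linearity, common-gain cancellation in %MVC) hold at 1e-9.
* Edge handling extends the signal by odd reflection and starts every
  section at its steady state for the first sample, so a constant passes
  through unchanged and short recordings have no start-up transient.
* Zero-phase low-passing a rectified signal can undershoot; residual
  negative samples are clamped to 0 (the envelope is interpreted as
  nonnegative neural energy) and the clamping extent is reported in the
  `"clamp"` attribute.
* The MVC percentile interpolates linearly between order statistics
  (`stats::quantile` type 7) — stated because published pipelines rarely
  say, and it changes the reference at the 0.1 % level.
* The MVC trial is processed with the identical chain before the percentile
  is taken, keeping the reference commensurate with the task envelope.

## Segmentation and alignment

Task phases come either from timed boundaries (`timed_phases()`, for
protocol-timed static tasks) or from the joint-rotation signal
(`detect_phases()`): a hysteresis comparator on the trunk angle (default
threshold 15°, the engagement angle typical of back-support devices, with
2° hysteresis and a 0.25 s minimum dwell against chatter) finds bent
intervals, and an angular-rate criterion (plateau when |rate| < 2°/s on a
50 ms smoothed angle) splits each into bending, position holding, and
rising up. The rate smoothing trades boundary sharpness for robustness on
real signals; on ideal trapezoids the plateau edges land within a few
samples of truth, and the tests assert exactly that tolerance. Segments are
stored as 1-based inclusive `[start, end]` index ranges, strictly
increasing, so that phases partitioning a record sum exactly.

One consequence worth knowing: a threshold-segmented "upright" interval
includes whatever the device does below the detection threshold. In the
worked examples the simulated device already acts during early trunk
flexion, so the upright segment preceding the bend shows a real, elevated
OII — that is a property of threshold segmentation, not an artifact.

Because the trend subtracts envelopes pointwise, the two conditions must
have the same number of samples in every phase. `time_normalize()`
resamples each phase onto a fixed count (default 1000, generous for a
2.5 Hz-band envelope over phases of seconds) by linear interpolation —
chosen over splines because it cannot overshoot, preserving nonnegativity —
and `align_pair()` applies it to both conditions after checking the phase
label sequences match. Per-phase indices are unchanged by this resampling
to well under half a percentage point (tested); full-task indices are
computed *on the aligned grid*, which weights every phase equally by
construction — that is the method's own definition of the full-task
comparison, but it is worth remembering when phase durations differ
greatly.

## Classical indices and diagnostics

`pv_table()` reports mean- and max-based PV per scope, with per-segment
maxima taken independently per condition — deliberately mirroring standard
practice including its failure mode. `peak_mismatch_check()` then inspects
which phase each condition's maximum falls in; if they differ, the
full-task max comparison mixes different sub-activities and the table row
is marked `reliable = FALSE` rather than silently reported.
`amplitude_density()` (Gaussian KDE, Silverman bandwidth by default)
visualizes how far the amplitude distribution is from normal, i.e. how much
meaning a mean- or percentile-based PV can carry; a zero-variance envelope
degenerates to a flagged point mass instead of an error.

## The synthetic generator, and what passing tests mean

`trial_spec()`/`simulate_trial()` generate a complete cell: a C¹ trunk-angle
trajectory (cosine ramps to a 60° bend, 8 s hold by default), a baseline
envelope built from per-phase shapes (raised-cosine-squared bumps peaking
at 80 %MVC for bending/rising, a 5 %MVC cosine-tapered plateau for holding,
2 %MVC tonic baseline upright — magnitudes on the scale of published
back-muscle tables), and raw EMG as a 30–400 Hz band-limited Gaussian
carrier amplitude-modulated by that envelope. The Exo condition multiplies
the envelope by a per-phase ratio α (default 0.71/0.81/0.90, mirroring
published per-phase overall indices of roughly 29/19/10 %), smoothed across
boundaries with a 100 ms cosine kernel so the envelope filter has no steps
to ring on. Multiplicative assistance keeps the ground truth closed-form:
per-phase OII = 100(1−α). Trial-to-trial amplitude variability enters as
slow (≤1 Hz) multiplicative jitter with 5 % relative s.d. Every output is a
pure function of the spec and seed.

The generator emulates what the indices need and no more. It does not model
motor-unit physiology, electrode shift, crosstalk between muscles,
inter-muscle coordination changes, additive device artifacts, or
non-multiplicative assistance. Recovery tests passing therefore show that
the pipeline correctly extracts a multiplicative envelope ratio from
realistic noise — not that any real exoskeleton behaves multiplicatively.
Within one simulated trial the slow jitter is correlated over seconds, so
single-trial per-phase indices scatter by a few percentage points; the
recovery experiment in the test suite averages 20 seeds and lands within
2 percentage points of truth. Problem sizes throughout the tests — 14–18 s
trials at 1 kHz, 1000 samples per aligned phase, 20-seed recovery, 1000
randomized pairs for the identity check — were chosen as the smallest
sizes at which the statistical checks are stable.

## Known limitations

* Indices are undefined over segments where the baseline envelope
  integrates to zero; such segments abort with a degenerate-input error
  rather than returning infinities, and near-silent muscles make per-phase
  indices noise-dominated (visible in the upright segments of the worked
  examples).
* The angle-based segmenter assumes one plateau per bent interval; bent
  intervals with multiple sub-plateaus are labelled by the longest one.
* Alignment is phase-wise linear resampling; there is no dynamic time
  warping, by design — within-phase timing differences between conditions
  are part of what the trend is supposed to show.
* Group aggregation is descriptive (mean, s.d.); no inferential statistics
  are provided.
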
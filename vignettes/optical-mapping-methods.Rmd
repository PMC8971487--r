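---
title: "Analysing cardiac optical mapping movies with omapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cardiac optical mapping movies with omapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omapr)
```

## The measurement problem

Cardiac optical mapping images the electrical activity of intact heart
preparations through potentiometric (or calcium-sensitive) fluorescent
dyes, yielding a movie in which every pixel carries an optical action
potential (OAP).  From such a movie one wants, per pixel: when the tissue
activated, how long the action potential lasted (APD), how fast the wave
travelled (conduction velocity, CV), whether consecutive beats alternate
(APD alternans), how self-similar the rhythm is (optical wave similarity,
OWS), and which frequency dominates the signal (dominant frequency, DF —
the workhorse statistic during fibrillation).  `omapr` implements this
chain end to end for MAT-container movie stacks, and ships a kinematic
simulator whose ground truth is exact, so every stage is testable without
any experimental download.

ANEPPS-family voltage dyes emit *less* light on depolarisation at the
long emission wavelengths used, so voltage movies enter the pipeline with
`polarity = "inverted_voltage"` and are flipped to upstroke-positive
per-pixel before anything else.  The inversion reference is the per-pixel
maximum, not a global maximum, so resting-brightness gradients across the
image do not distort relative amplitudes.

## Preprocessing

**Spatial filtering.** Each frame is convolved with a 3x3 sampled
Gaussian kernel (sigma = 1.5 pixels, weights normalised to sum 1).  At
image borders and mask edges the kernel is truncated and renormalised
rather than padded: padding (zero or reflected) would let values from
outside the tissue bleed into edge pixels, which matters because masks in
whole-heart preparations hug anatomical boundaries.  Renormalised
truncation preserves constants exactly and keeps each output a convex
combination of genuine tissue samples.

**Baseline correction.** Slow drift (photobleaching, perfusion movement)
is removed per pixel by a top-hat filter: the baseline is the grey-scale
morphological opening of the trace — a moving minimum followed by a
moving maximum with a flat structuring element — and is subtracted.  The
element length converts from milliseconds to the nearest odd sample count
(so the opening is centred) and must be at least 3 samples.  The opening
of any structure *narrower* than the element is its surrounding baseline,
so action potentials pass through unchanged while drift on longer time
scales is tracked and removed; a flat trace maps to exactly zero.  The
kernel must however be *longer than the optical AP width*: a kernel
shorter than the AP carves into the plateau and systematically shortens
long action potentials.  The package defaults (100 ms for mouse profiles
with ~40 ms APDs, 200 ms for guinea pig with ~110 ms APDs) respect this
rule, and the validation grid scales the kernel as
`max(profile default, 2.2 x APD)` for the same reason.

**Tissue masking.** The default criterion keeps pixels whose temporal
signal amplitude reaches at least a fraction (default 0.3) of the
95th-percentile amplitude; an Otsu threshold on the time-averaged image
is the alternative.  Amplitude is measured robustly, as the 1st-to-99th
percentile range of the pixel's 5-frame moving-average trace (used for
segmentation only — the analysis path carries no temporal filtering).
Two failure modes shaped this: a plain max - min range grows with
recording length under noise (the extremes of thousands of noise samples
span ~6.5 noise SDs) and at SNR 10 admits background wholesale, while
*spatial* pre-smoothing either bleeds a halo of background into the mask
(Gaussian) or clips convex corners of the tissue (median); per-pixel
temporal smoothing has neither problem.  Only the largest 4-connected
component survives — stray noisy pixels and detached blobs are
discarded — and holes are deliberately *not* filled, because lumina and
valve shadows must stay excluded.  With the 0.3 default the simulator's
known geometry is recovered with over 99% of truly active pixels and
under 1% false inclusions across the noise range studied (SNR 10 and
up).

## Beats, cycle lengths, ensembles

Beat detection runs on the mask-averaged global signal: local maxima with
topographic prominence of at least 0.4 of the signal amplitude, separated
by at least 40 ms, the more prominent candidate winning conflicts.  For
pipeline use each beat time is then refined to the upward crossing of a
*common* reference level (baseline plus half the median beat amplitude).
Two reasons: the raw argmax of the global signal wanders by tens of
milliseconds when short APs are dispersed over a long activation spread
(the systolic hump is then broad and flat), and a per-beat 50% level
moves with beat-to-beat amplitude alternation, imprinting a spurious
period-2 component on the measured cycle lengths.  The shared level rides
the rising edge, which is identical across beats of the same rhythm.

Pacing-cycle-length (PCL) groups are found by a running-median scan over
successive cycle lengths: a new group opens when an interval deviates
from the current group's running median by more than 5 ms — half the
10 ms step of the ramp pacing protocols the datasets use, so adjacent
ramp stages can never merge while singleton ectopic intervals isolate
themselves.  A group's nominal PCL is the median of its cycle lengths
rounded to 1 ms.

For morphology measurements the last 10 beats of a group are ensemble
averaged (fewer if fewer exist).  Windows are aligned on each beat's
global-signal upstroke midpoint — midpoints interpolate to sub-sample
precision and are robust to plateau noise, unlike peaks — snapped to the
nearest frame, spanning 20% of the PCL before to 90% after the alignment
point.  A final beat whose window would run into the next ramp stage is
excluded so ensembles never mix PCLs.  Alternans and OWS are computed on
single (non-averaged) beats, since averaging would cancel exactly the
beat-to-beat variation they quantify.

## Morphology measures

**Activation time** is the depolarisation midpoint by default: the first
upward crossing of 50% of (peak - baseline) before the peak, linearly
interpolated between samples.  The maximum-upstroke-velocity instant
(earliest maximum first difference, no interpolation) is available as an
option; it is the classical electrophysiological marker but quantises to
the frame grid, which at low sampling rates renders large regions
apparently simultaneous and their CV undefined — the reason midpoint is
the default here.  Activation maps are re-zeroed to the earliest defined
pixel.

**APD** runs from the maximum-upstroke-velocity instant to the first
interpolated downward crossing of the `level`% repolarisation level after
the peak (APD80 by default).  The amplitude baseline is the *median* of
the pre-upstroke segment of the window.  A pre-upstroke *minimum* was
considered and rejected: the minimum of ~40 diastolic noise samples sits
about two noise standard deviations below the true diastolic level, which
lifts the computed repolarisation level and — on shallow repolarisation
slopes — biases APD upward by ~2 ms at SNR 10.  The median is identical
on clean traces, unbiased under symmetric noise, and still robust to
windows that clip the tail of the previous beat (which is what rules out
a diastolic mean).  Level crossings are interpolated; the upstroke
instant is not (finite differences live on the frame grid), and
upstroke-slope ties resolve to the earliest frame.

**Heterogeneity** of any map is `(P95 - P5) / P50` over defined pixels,
with linearly interpolated percentiles — unitless and scale invariant.

**Alternans** (`dAPD80`) measures APD on every single beat of a group and
takes the absolute difference between consecutive beats, averaged over
the pairs (the final pair alone is an option).  A pixel in which any
single-beat APD is undefined is undefined — these are the blanked regions
of an alternans map.

## Conduction velocity

CV comes from the activation map by the multi-vector (local surface fit)
method: in every 5x5 pixel window a polynomial activation surface
`T(x, y)` is least-squares fitted and the velocity is
`v = grad T / |grad T|^2`, converted to cm/s via the pixel size.  The
default surface is a plane — 25 points for 3 parameters is well
conditioned, and a first-order model is unbiased on locally planar
wavefronts; the full second-order surface is available
(`order = "quadratic"`) for strongly curved fronts.  Pixels with fewer
than 12 defined neighbours, rank-deficient fits (collinear support), or
speeds outside 1-200 cm/s are undefined: near-zero gradients (apparent
simultaneous activation, e.g. transmural breakthrough regions) would
otherwise produce arbitrarily large speeds.  Coordinates are image
convention (x = column, y = row, y downward), and velocity points from
early to late activation.  The reported CV of an analysis is the
arithmetic mean speed over an ROI; restricting that ROI to the
neighbourhood of the pacing site avoids far-field inflation by
breakthrough wavefronts (see below).

## Rhythm measures

**Dominant frequency.** The mean-subtracted trace is Hann-windowed,
zero-padded to `ceiling(frame_rate / 0.05 Hz)` samples and transformed by
FFT; DF is the frequency of maximum magnitude-squared power within
0.5-50 Hz, exact ties resolving to the lowest frequency.  The padded grid
spacing stays at or below 0.05 Hz for all three acquisition profiles.  DF
is invariant to amplitude scaling and offsets; a flat trace has no
spectral peak and is flagged undefined.

**Optical wave similarity.** Single-beat windows (upstroke midpoint
- 20 ms to + 0.9 PCL, truncated to a common length) are
amplitude-normalised to [0, 1]; OWS is the weighted sum over beats of
each beat's mean cosine similarity to all others, clipped to [0, 1].  The
literature derivation of the weights is not reproduced here: the package
defaults to uniform weights (a plain mean of per-beat mean similarities)
and exposes the weight vector as an argument so alternative schemes can
be injected.  This is the module's largest interpretive decision; uniform
weighting preserves the defining behaviour (1 for perfectly repeating
beats, toward 0 in fibrillation) and every invariance the measure should
have (beat-order symmetry, uniform affine invariance).

## The synthetic-data generator

The simulator is kinematic by design: a template action potential is
launched from each stimulus and arrives at each pixel after
`distance / speed`, with no reaction–diffusion model behind it — which is
precisely why every ground-truth quantity is closed-form.  The template
has a sigmoid upstroke (unique maximum-slope instant at its centre) and a
*linear* repolarisation whose slope is set so the 20% downward crossing
falls exactly APD80 after the upstroke instant; linearity is what makes
the APD80 ground truth exact rather than approximate.  Geometries are
planar (any angle) or radial; the pacing schedule is an explicit list of
(PCL, beat count) stages — published ramp descriptions leave terminal
PCLs ambiguous, so the generator never guesses — optionally with a
per-stage APD80 to emulate restitution down a ramp.  Beat-to-beat APD
alternation, i.i.d. Gaussian noise (SD expressed as a fraction of the AP
amplitude, so SNR = 1/noise_sd), sinusoidal baseline drift, dye polarity,
and a breakthrough term are all programmable, and the same seed always
reproduces the movie bit for bit while ground truth never depends on the
noise.

The breakthrough term compresses apparent activation delays with distance
from the origin, `delay / (1 + boost * r)` with `r` the normalised
distance, making apparent speed grow as `(1 + boost * r)^2`.  It is a
phenomenological stand-in for transmural wavefronts surfacing far from
the pacing site — enough to reproduce the qualitative artefact (whole
surface mean CV exceeding the near-pacing-site mean) without claiming to
model transmural conduction.

An irregular-movie generator emulates fibrillation-like regimes: spatial
domains each emitting a beat train at their own frequency with
multiplicative interval jitter and per-beat amplitude/shape variation;
the true per-pixel DF is the domain frequency.

What the simulator does *not* emulate — curved and colliding wavefronts,
repolarisation gradients, motion artefact, shot (Poisson) noise,
fractionated electrograms — bounds what green tests mean: they show the
measurement chain is correct and well conditioned under the stated
conditions, not that it is robust to every pathology of real recordings.

## Validation conditions and numerical choices

The headline validation (`recovery_table()`) crosses the three
acquisition profiles (1 kHz/156 um/51x51; 0.987 kHz/71.4 um/45x45;
0.5 kHz/320 um/64x64) with speeds {20, 50, 100} cm/s, APD80
{40, 80, 110} ms and SNR {Inf, 20, 10} — 81 conditions, each a full
simulate-and-analyse round trip of about 1.5-4 s of recording (13 beats
at one PCL), a problem size chosen to keep the whole grid a few minutes'
work.  Condition details, each fixed once:

* **PCL** starts from the profile's baseline (110/120/160 ms) and is
  raised in 10 ms steps until a beat completes everywhere before the next
  stimulus and fits the default ensemble window — slow waves crossing the
  guinea-pig field at 20 cm/s take over 100 ms, which no physiological
  160 ms PCL can accommodate together with a 110 ms APD.
* **Alternans delta** is 10 ms, concurrent with every condition, so the
  alternans map is validated under the same noise as everything else.
* **13 beats** (an odd count) make the interval count even, so the
  period-2 peak-time shift that alternans induces contributes both
  branches symmetrically to the group's median cycle length.
* **Upstroke duration** is `max(5 ms, 4 sampling intervals)`.  Optical
  upstrokes are blurred over several milliseconds by scattering and pixel
  integration, and the sub-sample midpoint interpolation that CV accuracy
  rests on is meaningful only if the rise spans a few samples: with a
  1-sample rise the crossing-interpolation error forms a spatial sawtooth
  comparable to the activation gradient itself at 100 cm/s, and the
  convexity of `1/|grad T|` then inflates mean CV by several percent.
  This is the same sampling-rate limitation that makes
  maximum-upstroke-velocity activation times problematic on real
  high-rate, small-pixel recordings.
* The CV summary ROI excludes a 3-pixel border: the wave's entry edge has
  no upstream neighbours, so border fits there are one-sided and biased
  (visibly inflated first columns in a planar run) — the synthetic analog
  of restricting analysis area on real hearts.

Degenerate inputs are defined, not accidental: flat traces normalise to
an error, constant movies have undefined DF everywhere, zero gradients
give undefined (not infinite) velocities, single-beat groups give
all-undefined OWS maps with a warning, and batch pipeline runs log and
skip failing movies while single-movie runs re-raise.

## Known limitations

MAT reading covers Level-5 (v6/v7, including compressed elements, either
endianness) natively and v7.3 through an external `h5py` bridge; the
deposited containers' internal variable names and dimension order are not
standardised, so the loader exposes explicit overrides rather than
guessing silently.  The OWS weights are uniform by default (see above).
No temporal filtering is applied anywhere, matching the analysis
conventions the package emulates; no motion correction, phase mapping or
rotor tracking is attempted.  Group-level statistics across hearts
(ANOVA and friends) are out of scope — the pipeline ends at per-recording
summary tables.
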
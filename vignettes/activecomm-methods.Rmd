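---
title: "Methods: closed-loop commutation control and wide-field calcium preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop commutation control and wide-field calcium preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activecomm)
```

## The problem

Miniaturized neural recording devices on freely moving mice are tethered:
power and data run through a cable to a slip-ring commutator above the
arena. As the animal turns, torsion accumulates in the cable unless the
slip ring is rotated to follow; in long arenas the commutator must also
translate to stay above the animal. This package implements the
computational core of a commutator that is driven by computer vision
alone: an overhead camera plus a markerless pose tracker yields, per
frame, the head and tailbase keypoints and their confidences, and the
controller turns those into rotation and translation commands. Everything
downstream of the pose stream — the controller, a kinematic stage
simulator, the tracking-evaluation protocol, the wide-field calcium
preprocessing chain used to verify that compensation does not perturb
imaging, and the peri-event bootstrap statistics — is implemented and
testable on synthetic data with known ground truth.

## Heading accumulation and rotation compensation

The heading direction is the unit vector from tailbase to head. For two
consecutive accepted estimates the magnitude of the heading change comes
from the dot product and its direction (clockwise vs counter-clockwise)
from the z component of the cross product. We work in image coordinates
(y down), and define clockwise-in-the-image as positive. Numerically the
magnitude is evaluated as `atan2(|cross|, dot)` rather than `acos(dot)`:
the two are identical in exact arithmetic, but the arccosine loses
relative precision near 0 and 180 degrees, and the controller integrates
thousands of these deltas per trial. Exactly antiparallel vectors are a
genuine tie; we return +180 (clockwise), an arbitrary but fixed and
documented choice.

Per-frame deltas accumulate in a signed register. When the magnitude of
the register reaches the rotation threshold (90 degrees in the circular
arenas, 225 on the linear track — the presets in
`controller_config()`), a `rotate_by` command carrying the **full
accumulated angle** is emitted and the register resets to zero. The
alternative — rotating by exactly the threshold and keeping the excess —
is supported in principle by the same machinery but is not the default:
commanding the accumulated amount keeps the long-run cable twist centered
on zero. Threshold comparisons use a 1e-9 degree tolerance so that
streams constructed to hit the threshold exactly are not derailed by
floating-point accumulation error.

Three gates precede accumulation: a stride (an estimate is consumed only
every `stride` frames, default 5), a confidence gate (both keypoints
strictly above 0.9 by default), and a degeneracy check (coincident
keypoints). Failed frames simply advance time; accumulation pauses rather
than extrapolating. A delta taken across a gap assumes less than 180
degrees of net rotation in between, so gaps longer than one second raise
a warning. Because deltas telescope, the sum of all emitted commands plus
the final register equals the net true rotation whenever every frame is
accepted — a conservation law the tests assert to 1e-6 degrees.

## Translation compensation and the stage simulator

On the 1.2 m linear track the maze is divided into eight equal virtual
segments (15 cm each) and the head's segment is computed per accepted
frame with half-open binning, the far end clamped into the last segment.
A segment change commands the stage to the new segment's center; there is
no hysteresis band by default, so oscillation across a boundary commands
a move per crossing (a configurable dead band would be the first thing to
add if that proved noisy in practice).

The simulated stage executes commands FIFO at constant speed — 100 deg/s
rotation, 0.2 m/s translation, no acceleration ramp, translation clamped
to the track ends as the physical limit switches would. Cable twist is
accounted per frame as the controller's total accumulated heading minus
the commutator angle. For a gated trajectory the twist magnitude is
bounded by the threshold (the register can hold that much), plus one
outstanding command (at most threshold plus one delta, while the motor
works through it), plus the current frame's delta; the tests assert this
bound over 50 random-walk trajectories.

## Synthetic trajectories and movies

The trajectory generator is first-class, tested code, not a fixture. It
produces a rigid two-point body (60 px head-to-tailbase) whose heading
follows a Gaussian turn-rate random walk (default SD 60 deg/s, mean
speed 0.1 m/s — a mouse at a walk) inside a circular, linear or open
arena at camera rates of 6–10 fps, with the continuous unwrapped heading
as ground truth. A scripted pirouette mode pins the net rotation to an
exact multiple of 360 degrees; the 720-degree clockwise pirouette at 10
fps uses 361 frames so the per-frame step is exactly 2 degrees and the
90-degree threshold divides the turn into eight equal commands.
`corrupt_poses()` models occlusion (confidences drawn below the gate) and
tracker jitter.

The movie generator emulates dual-illumination wide-field imaging:
alternating blue (calcium) and green (reflectance) frames at 30 fps
interleaved (15 per channel), Gaussian-footprint cells with
exponential-decay transients (tau 1 s, rate 0.2 Hz), a shared slow
multiplicative hemodynamic artifact on both channels, a static smooth
baseline pattern standing in for vasculature and uneven illumination
(this is what anchors motion correction), additive Gaussian noise, an
exact count `round(outlier_frac * T)` of zeroed LED-dropout frames, and
per-frame integer rigid shifts. Shifts are applied toroidally so that a
planted shift is exactly invertible — a deliberate simplification; real
frames lose content at the edges. What the generator does **not**
emulate: photorealism, non-rigid motion, behavioral states (rearing,
grooming), frame drops, or spatially structured hemodynamics — so green
tests here show the pipeline's arithmetic is right, not that it is robust
to everything real data does.

## The calcium preprocessing chain

The chain runs in one fixed order — segregate channels, motion-correct,
bin, mask, DF/F with reflectance correction, temporal band-pass, spatial
smooth, per-pixel z-score — and `run_calcium_pipeline()` rejects
out-of-order stage requests rather than silently reordering.

**Channel segregation.** Two-means clustering on per-frame mean
intensity, initialized at the intensity extremes so the result is
deterministic; the brighter cluster is blue by convention (configurable).
Frames beyond 5 robust SDs (MAD) of their cluster center are relabeled
outliers; clusters whose centers are closer than twice the pooled robust
SD are declared non-separable. After outlier removal each blue frame is
paired with its nearest-in-time green frame.

**Motion correction.** Per-frame integer translation from the peak of
the FFT cross-correlation against a template (mean of the first 10
frames, or a chosen reference frame). Integer resolution is deliberate:
the displacement question the pipeline answers is whether compensation
epochs move the field of view, and the planted-shift tests require
exactness, which subpixel interpolation would trade away. Against a
blurred mean-of-first-k template recovery can be off by one pixel; the
exactness tests therefore use a reference frame.

**Binning.** Frames are compressed to 80% linear size by exact
area-overlap averaging, which preserves the frame mean by construction.

**DF/F and reflectance correction.** Per pixel,
\(\Delta F/F = (F - F_0)/F_0\) with \(F_0\) the per-pixel trial mean
(default) or a rolling percentile. The correction divides out the shared
hemodynamic fluctuation ratiometrically,
\[(1 + \Delta F/F_{blue})/(1 + \Delta F/F_{green}) - 1,\]
which cancels a shared multiplicative artifact exactly; a per-pixel
regression subtraction is available behind a switch. Ratiometric is the
default because the generator's artifact — like absorption changes in
tissue — is multiplicative.

**Band-pass.** Chebyshev type-I, order 2, 0.1–5 Hz, applied
forward-backward (`signal::filtfilt`) for zero phase. The pass-band
ripple default is 0.2 dB: zero-phase filtering applies the filter twice,
so a 0.5 dB design ripple would dip the two-pass pass-band gain to 0.89,
below the 0.9 floor we hold the filter to at 1 Hz; at 0.2 dB the
two-pass gain at 1 Hz is 0.95.

**Spatial smoothing and z-scoring.** The "7-pixel neighbor average" is
read as a 7×7 window mean restricted to in-mask pixels (a radius-3 disk
kernel is the configurable alternative); masked-out neighbors never leak
into the average, so a constant field stays constant up to the mask
edge. Z-scoring uses the population (N-denominator) SD; zero-variance
pixels are set to zero and counted in QC. Per-trial masks combine by
majority vote (`average_masks()`, vote fraction 0.5; 1.0 gives the
intersection).

The per-channel rate is half the interleaved acquisition rate; both are
configurable (defaults 30 and 15 fps).

## Peri-event statistics

`peth()` averages an ROI-mean z-scored trace in a window around each
commutation epoch onset (default 2 s before to 10 s after — wide enough
to cover a 720-degree rotation at ~100 deg/s). The null is built by
drawing `n_boot = 1000` surrogate PETHs, each averaging as many randomly
placed windows as there are real events, so the surrogate distribution
has the same sampling variance as the real average; draws come from the
entire trial including the event epochs (an exclude-events variant is
available). Group-matching is the choice that makes the null SD scale as
\(1/\sqrt{n_{events}}\), which the tests verify against the CLT.

Significance per timepoint compares the empirical two-sided tail
probability — add-one estimator, floor \(1/(n_{boot}+1)\) — against the
Bonferroni level \(\alpha/m\) with \(m\) the number of timepoints by
default (multiply by the ROI count when correcting across regions). Note
the interaction between the floor and the correction: with 1000
bootstraps, a window longer than about 20 timepoints at \(\alpha = 0.05\)
pushes \(\alpha/m\) below the attainable p-value, and nothing can be
flagged; either shorten the window, raise `n_boot`, or use the SD-threshold
variant. The demo keeps its window short for exactly this reason. Under
the null (events placed at random in a stationary trace) the family-wise
false-positive rate over 200 replicates sits at or below the nominal
0.05, mirroring in form the finding that active compensation introduces
no event-locked artifact.

## Problem sizes and determinism

The test suite and the acceptance script run everything on synthetic
data sized so the full battery completes in well under a minute on one
core: 10,000 random vector pairs for the angle oracle, 361-frame
pirouettes, 50 30-second random walks, an 18,000-frame 8×8 movie for
segregation (matching a 10-minute session's frame count at the
acquisition rate), a 200-frame 64×64 stack for motion correction,
800-frame 24×24 movies for the correction-recovery study, and 200
replicate traces for the bootstrap calibration. Every stochastic
component takes an explicit integer seed and restores the caller's RNG
state; the demo bundles are byte-identical across reruns with the same
config and seed.

## Known limitations

- Pose streams come from files or generators; no network inference, no
  video decoding.
- Movie I/O covers TIFF stacks and in-memory arrays.
- Motion correction is rigid and integer-valued; no non-rigid warping.
- The controller pauses on gated frames rather than extrapolating
  heading; sustained occlusion with fast turning can alias across a gap.
- The stage model has no acceleration ramp or backlash; real steppers
  will lag the constant-speed idealization slightly.

```{r demo, eval = FALSE}
# End-to-end closed-loop demo: writes run logs, command CSVs, twist trace
cfg <- read_run_config(list(seed = 1, out_dir = tempfile("demo")))
demo_closed_loop(cfg)
demo_calcium(cfg)
```
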
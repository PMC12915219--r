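---
title: "Simulation-trained time-of-flight tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-trained time-of-flight tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutomo)
```

## The problem

Through-transmission ultrasound tomography reconstructs a spatial map of the
local speed of sound (SoS) inside an object from the first-arrival travel
times (ToF) of pulses crossing it. In the laser-ultrasound configuration this
package models, a 16-element generation array and a 16-element detection
array face each other across a 77.4 mm water-filled immersion tank (2 mm
pitch, 30 mm aperture). The object is a tissue-mimicking cylindrical gel
phantom (1455 m/s) carrying one or two fluid inclusions (water 1480 m/s or
10 wt% glycerol 1538 m/s) — speed contrasts as small as 25 m/s, comparable
with contrasts between soft tissues. `lutomo` implements the full software
side of that experiment: phantom synthesis, travel-time simulation, onset
picking from waveforms, a convolutional reconstruction network trained purely
on simulated data, and the evaluation metrics.

## Phantom model and rasterisation

Phantoms are sampled from discrete uniform distributions on a 0.6 mm lattice:
per-axis centre offsets in {±1.2, ±0.6, 0} mm (the lattice is applied
independently per axis), diameters 9.7–29.6 mm for single-inclusion phantoms
and 23.6–29.6 mm for two-inclusion phantoms, inclusion diameters 4.8–11.5 mm,
and the two categories drawn with probability 0.5 each. Inclusion positions
are continuous: uniform over the disk of admissible centres. Two constraints
are enforced by rejection sampling (capped at 10,000 attempts): every
inclusion keeps at least one coarse pixel of gel to the phantom boundary, and
the two inclusions of a two-inclusion phantom keep the same margin between
each other. The containment constraint is part of the sampling model; the
non-overlap margin is this package's own addition, chosen so that rendered
regions remain separable by segmentation.

Maps are rasterised on a cell-centred square grid (default 128 × 128 over
77.4 mm, i.e. 0.6047 mm pitch — the 0.6 mm value above is a parameter-lattice
step, not the pixel pitch) by pixel-centre membership tests, innermost region
winning. The second acquisition view rotates the inclusion layout 90°
counter-clockwise about the phantom centre (geometry rotation, which we take
as canonical; rotating the rendered raster differs only in boundary pixels,
and a regression test bounds that difference). Class coding maps
gel → 0, water → 0.5, 10 wt% glycerol → 1; the recoding is bijective and
exactly invertible.

## Travel-time simulation

First-arrival fields solve the isotropic eikonal equation |∇T| = 1/c(x) with
a first-order upwind fast-marching method: the standard two-axis quadratic
update, a binary-heap front with ties broken by (time, row-major index) so
the accepted order is deterministic. Because a point source is singular for
first-order schemes, the solver initialises T = distance/c analytically on a
disk of 3 coarse pixels around the source (the source neighbourhood is
always water in this geometry).

The coarse field is interpolated onto a `factor`-times denser grid (default
5, so 128 → 640) bilinearly. Bilinear rather than higher-order interpolation
preserves monotonicity and, for odd factors, the coarse nodal values exactly;
edge cells extrapolate linearly so affine fields are reproduced everywhere.
Rays are then traced from each detection point down the gradient of the fine
field (quarter-fine-pixel steps, central-difference gradients, bilinear
lookup). The descent terminates on entering the analytic initialisation disk
— inside it the field is exactly radial, so the closing straight segment to
the source is the true geodesic; terminating earlier, e.g. at one fine pixel,
can stall against the domain boundary where the clamped gradient turns
parallel to the edge. The ToF entry is the trapezoidal slowness line-integral
along the polyline, which is less sensitive to the O(h) fast-marching error
than the interpolated field value; the field value remains available and is
used as a fallback (with a warning) if a descent fails.

Verification is oracle-based: homogeneous media against distance/c (every
element pair within 1%), exact slowness scaling, two-layer refraction against
the Fermat closed form, reciprocity under source–receiver exchange (≤ 0.2%),
monotonicity under speed increases, and bracketing between lattice Dijkstra
shortest paths on coarse (over-estimating) and fine (near-optimal) stencils.

## Synthetic waveforms

The measured laser-ultrasound pulse has an asymmetric spectrum: peak at
6.56 MHz with −6 dB edges at 1.94 and 11.98 MHz. A single Gaussian-modulated
cosine cannot place an off-centre peak inside an asymmetric band, so the
synthesiser uses a split-Gaussian magnitude spectrum (separate half-widths
below and above the peak, each fitted to its −6 dB edge) with zero phase,
evaluated as a cosine sum so arrivals can be placed with sub-sample
precision. The pulse onset — the "true ToF" in every test — is defined as
the envelope's −40 dB leading point. A-scans sample at 100 MS/s (dt = 10 ns,
well above Nyquist for the 12 MHz band), span the pair's physics window
± 3 µs, and add white Gaussian noise specified as peak-amplitude-to-RMS SNR
in dB. An optional reverberation echo (delayed, scaled copy of the pulse)
emulates the multipath events present in experimental data; it is off by
default and enabled in the picker comparison bench, because those events are
precisely what defeats a single-stage full-trace correlation picker. The
single-arrival model deliberately omits attenuation, diffraction and
directivity: it exercises the picker's contract, not the physics of
propagation, and results on it do not certify performance on real waveforms.

## Two-stage onset picking

Signals are band-passed 1–7 MHz with a zero-phase (forward–backward)
fourth-order Butterworth — zero phase avoids group-delay bias in onset
position. A physics window [d/1538, d/1455] from the pair geometry and the
velocity envelope bounds the admissible arrival. Stage 1 computes the
population-moment kurtosis in a 2 µs sliding window (values anchored at the
window's leading edge; the trace is dated at the trailing sample, since it is
the newest sample entering the window that drives the kurtosis rise) and
takes the first strict local maximum above 55% of the in-window peak, falling
back, with a flag, to the first threshold crossing.

The kurtosis marker of a band-limited pulse sits a rise-time-dependent delay
(here roughly 0.3 µs) after the −40 dB onset. Both the signal and its water
reference share one pulse shape, so this delay cancels in the difference of
their kurtosis markers: stage 2 centres its refined window (0.08 µs before to
0.1 µs after) on the reference's analytic arrival time shifted by that
marker difference, then maximises the unnormalised cross-correlation against
the reference over the lags that keep the candidate arrival inside the
window. Ties resolve to the smallest |lag| (flagged); results outside the
physics window are clipped and flagged. The picked time is
`referenceTof + lag · dt` with `referenceTof = distance/1480` taken
analytically. This differential-marker construction is the package's
design choice for anchoring the refined window; it preserves the published
window sizes and threshold while making the two-stage pick unbiased on
synthetic signals (exact at SNR ≥ 30 dB in the round-trip test).

The single-stage baselines used in the comparison bench are the kurtosis
stage alone (its raw marker, bias included — it has no reference to
difference against) and the global cross-correlation argmax over the full
trace. On reverberating signals at 20 dB SNR the bench reproduces the
expected ordering: two-stage < single-stage kurtosis < single-stage
cross-correlation in mean absolute error. The published nanosecond error
figures for this comparison come from experimental waveforms and are not
numeric targets for the synthetic bench.

## ToF matrices and the network input

Each phantom yields two 16 × 16 ToF matrices (views at 0° and 90°). The
whole dataset is normalised by one geometry-derived constant — the longest
element-pair distance over the smallest velocity of interest,
√(77.4² + 30²) mm / 1455 m/s ≈ 57.05 µs — rather than the empirical dataset
maximum, so the scale is invertible and identical at training and inference
time without rescanning any dataset. The two views are stacked
block-diagonally into a 32 × 32 matrix `[T1 0; 0 T2]` and zero-padded into
the output frame (anchored top-left; any fixed placement is equivalent for a
learned network, but it must be identical at training and inference time, so
the convention is recorded in the dataset manifest).

## Network and training

The reconstruction network is fully convolutional: a stride-2 3 × 3
convolution for feature extraction, encoder residual blocks, four
down-and-up-scaling (DUS) units (stride-2 down path, 3 × 3 processing,
depth-to-space block-2 up path, additive skip), decoder residual blocks, a
long additive skip from the encoder output, and a linear 3 × 3 head whose
four channels are rearranged by depth-to-space to the full grid. All
activations are rectified linear; the output is linear and snapped to the
nearest class code (thresholds 0.25 / 0.75) post hoc, because the regression
target lives in [0, 1]. Channel widths and block counts are configuration
parameters: the published capacity (~1.15 × 10⁸ parameters) is a sizing
guide for the full-scale preset, not a test target.

Three fixed, architecture-level conventions help a small network train
quickly. The input is conditioned by subtracting the (analytically known)
normalised water-reference stack and scaling by a constant gain of 200 — the
conditioned input is zero for a water-filled tank and of order one for
phantom perturbations, which are otherwise ~10⁻² on the normalised scale.
The output bias is initialised at 0.5, the water class code, so the
background is correct from the first step. And every convolution feeding a
depth-to-space rearrangement uses sub-pixel (ICNR-style) initialisation —
its four sub-pixel channels start identical — because otherwise the output
remains speckled by checkerboard artefacts for the whole of a short training
budget. Training follows the published protocol: Adam, MSE loss, batch 16,
learning rate reduced ×0.5 after 8 epochs without validation-loss
improvement ("improvement" is taken to mean validation loss),
best-validation parameters retained, seed-deterministic data order and
splits (split identity is per phantom spec; overlap between train and
validation is an error).

The full-scale protocol (20,000 maps, 100 epochs, lr 10⁻⁴) targets GPU
hardware and is not reproduced here. The package's **desk preset** scales the
experiment to one CPU: 64 × 64 grid, 8 base channels, 200 training
phantoms, 30 epochs. At this scale 10⁻⁴ cannot converge in the ~700
optimiser steps available, so the desk preset raises the learning rate and
stabilises the faster optimisation with two standard devices: a global
gradient-norm clip and Polyak (exponential moving average) weight
averaging, with validation scored on the averaged weights (see
`deskPreset()` for the values; both are off in the full-scale
configuration). The schedule and loss are unchanged. Because a ~700-step
run occasionally lands in a visibly poor optimum, the desk protocol trains
two random restarts and keeps the one with the lower validation loss —
model selection strictly by validation, never by any held-out quantity
(`trainWithRestarts()`). Two further conventions exploit an exact physical
symmetry: transposing both stacked view blocks is precisely the acquisition
of the medium mirrored about the tank midline (source–receiver
reciprocity), so training doubles each batch with the mirrored twin of
every sample, and prediction averages the network output over an input and
its mirror. What desk-scale
results certify is property-level behaviour — gradient flow (a 16-sample
subset can be driven below 10⁻³ training MSE) and coarse parameter recovery
(phantom diameter from held-out synthetic inputs) — not the published
full-scale image quality.

## Evaluation metrics

Regions are segmented from class-coded maps by 4-connected components: the
phantom is the largest gel component; inclusions are non-gel components that
do not touch the image border and whose entire outer boundary is phantom gel,
ranked by area. Diameter is the longest axis-aligned pixel run through the
region times the pixel pitch (a maximum-calliper Feret alternative is
available behind a flag but is not the default, since pixel counting along an
axis matches the printed two-decimal values at 0.6047 mm pitch). The centre
combines the midpoints of the longest row-wise and column-wise runs — the
along-run midpoint fixes one coordinate accurately, and the orthogonal run
fixes the other; taking both runs is this package's reading of
"midpoint of the measured diameter", since a single run leaves its
cross-axis coordinate quantised to a whole pixel.

Comparisons report change = ground truth − reconstruction (mm and % of the
ground-truth diameter) and the Euclidean centre offset. All arithmetic is
carried at full precision; only reporting rounds, at two decimals, half away
from zero. The bundled printed measurement table of the four experimental
phantoms reproduces, through this code path, all of its published aggregate
statistics exactly; predicted inclusions are matched to ground truth by
nearest centre, unmatched predictions are counted as false positives, and a
map without a detectable phantom is a reported outcome, not an exception.

## Numerical choices and degenerate inputs

* Speed maps must be strictly positive; user-supplied maps are validated
  against a 1400–1700 m/s soft-tissue envelope.
* Zero-variance kurtosis windows are undefined (`NA`) and excluded from peak
  search; an all-undefined search range is an error.
* Correlation ties break to the smallest lag magnitude; run-length ties in
  diameter measurement break to the first run encountered (rows before
  columns).
* The rejection sampler raises after 10,000 failed placements rather than
  looping silently.
* Problem sizes in the test-suite: eikonal oracles run on 32–128 px grids,
  the picker bench on 500 trials, the network suite on the desk preset.

## Known limitations

* Isotropic media only; the locally interpolated anisotropic extension of
  the fast-marching family is out of scope.
* No full-waveform physics: the synthesiser places a single arrival (plus an
  optional echo); attenuation, diffraction, scattering and directivity are
  absent, so picker results on synthetic data bound, but do not measure,
  experimental performance.
* Circular two-dimensional phantoms only; no 3-D extension.
* The desk-scale network is a property check; reproducing published
  reconstruction quality requires the full-scale dataset and hardware.
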
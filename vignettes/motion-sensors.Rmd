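---
title: "Models and design of the mrmotion sensor pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the mrmotion sensor pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrmotion` studies three MRI-compatible motion sensors — a Pilot-Tone RF
transmitter, a single-element A-mode ultrasound (organ configuration
motion, OCM) sensor, and a Time-of-Flight (ToF) depth camera — together
with the signal processing and small neural networks that turn their raw
streams into physical motion estimates. Everything runs on a synthetic
phantom whose ground truth is known exactly, so every stage of every
pipeline is testable without access to scanner data. This vignette
explains the underlying models, the parameters that matter, the design
choices made where the design was genuinely open, and what the synthetic
results do and do not say about real acquisitions.

## The motion phantom

`make_breathing_phantom()` generates seeded motion trajectories and a
parametric 2D anatomy.

**Respiration.** Within each breathing cycle the superior–inferior liver
displacement follows `A sin(pi*u)^4` with `u` the cycle phase: a brief
inhalation peak and a long end-exhale plateau, which is the asymmetry
respiratory traces show in practice. Cycle period (default 4 s) and
amplitude (default 10 mm peak-to-peak) are jittered by 5% per cycle; a
slow sinusoidal baseline drift (0.5 mm, 60 s) is added. Deep breaths
scale a whole cycle by 2.5; coughs are 0.45 s transients of 30 mm
superimposed on the trace. With these defaults a 20 mm displacement
threshold retains normal breathing and removes only deep breaths and
coughs, which is how the gating rule is meant to operate. No published
quantitative waveform was available for these amplitudes; they were
chosen once as representative of abdominal breathing and are
configurable in `phantom_config()`.

**Anatomy.** The abdominal view (128×128 at 2.34 mm) contains a lung
region above a dome-shaped liver with dark vessels; positive
displacement shifts the liver inferiorly. The pelvic mid-sagittal view
is tissue-filled (no air background) with a bright elliptical bladder —
deliberately, because the bladder-area ground truth uses a single global
Otsu threshold, which must separate bladder from tissue rather than body
from air. Rendering is 3× supersampled and block-averaged, i.e. boundary
pixels take partial-volume values, so organ areas move continuously
between frames. Without this the rasterised area has ≈50 mm² of
quantisation noise, which would dominate the bladder-area error budget.

**Bladder geometry.** Pelvic-floor contractions squeeze the vertical
semi-axis `b`; the horizontal semi-axis keeps a fixed aspect ratio (plus
a 0.5% respiratory modulation), so the mid-sagittal area `pi*a*b` dips
by the configured fraction (default 35%) at full squeeze. In the A-mode
geometry the posterior bladder wall echo sits a fixed multiple of `b`
deeper than the anterior wall. This anchoring matters: it makes the echo
separation a subject-independent encoding of the bladder geometry, so an
area model trained on some subjects transfers to an unseen one. The
bladder interior is anechoic (urine), so no speckle is placed there.

**A-mode data.** Each column is a superposition of Gabor pulses (1 MHz
carrier, 0.6 µs Gaussian envelope) centred at round-trip sample
`round(2 z fs / c)` with `fs` = 20 MHz and `c` = 1540 m/s, with
exponential depth attenuation (0.01/mm). Discrete interfaces move with
respiration (0.3 mm per mm of liver displacement), one group in
anti-phase; 110 weak seeded scatterers through the first 55 mm emulate
tissue speckle. The speckle is what gives the band-median curves and the
cross-correlation tracker something to hold on to; without it the depth
profile is empty between interfaces and a median over a band is
motion-blind. The simulator is a scalar reflector model — no wave
propagation, beam profile, multiple scattering or speckle
decorrelation — which is sufficient to exercise the downstream
processing but says nothing about acoustic image quality.

**Radial k-space.** Spoke `k` is acquired at `(k-1)·TR` (TR 3.57 ms)
at golden-angle (111.246°) increments, the standard ordering for
stack-of-stars imaging; the 3D stack is collapsed to a single 2D
partition since the partition dimension adds nothing to per-line gating
logic. Each spoke is the exact (separable) non-uniform discrete Fourier
transform of the phantom image at that instant; motion states are
quantised to 0.05 mm and rendered images cached. At desk scale
(128×128, 256 readout samples) the exact transform is fast, so no
gridding approximation is needed anywhere.

The readout is 2× oversampled: 256 samples at the pixel bandwidth give a
sampled band twice the imaging band, and the Pilot-Tone must fall in the
outer half. At the radial protocol's 500 Hz/pixel this window is
32–64 kHz, so the radial default offset is 48 kHz; the fast calibration
protocol (1955 Hz/pixel) keeps an offset of 180 kHz, in the 100–250 kHz
range typical for clinical fields. Offsets inside the imaging band raise
a spectral-overlap error, mirroring how tone placement is chosen on a
scanner.

## Pilot-Tone pipeline

Tone extraction FFTs each line along readout and records the magnitude
peak within ±3 bins of the expected tone bin; a line fails a
peak-to-local-background ratio floor of 3, and if more than half the
lines fail, extraction aborts ("tone not detected"). Using magnitudes
makes the series invariant to global k-space phase. Multi-channel input
reduces to the channel with maximal mean peak.

The liver segmenter is a 2D U-Net trained with Dice loss, Adam at
learning rate 1e-4, batch size 10, and a 70–20–10 train–test–validation
split, contiguous in time within each subject so temporally adjacent
(nearly identical) frames cannot leak across splits. The architecture
uses 3 resolution levels, 4 base filters, two convolutions per encoder
block, one per decoder block, and nearest-neighbour upsampling — the
smallest configuration that segments the synthetic anatomy reliably
while 30 epochs over ~500 frames stay within a single-CPU budget (about
4 minutes; the whole-network forward/backward runs in single-precision
C++). Predicted masks are post-processed by hole filling and
largest-component selection, which is idempotent and leaves at most one
component. Boundary displacement is the median over columns of the
topmost mask row, times the pixel size, referenced to the series minimum
(end-exhale); the 20 mm gating threshold is interpreted relative to that
reference, which is configurable since no absolute reference was stated
with the rule.

The motion model maps a sliding window of 16 z-scored tone samples
(frame-averaged: each image frame receives the mean of the tone over the
lines acquired in its interval) to min–max-normalised displacement
through five hidden layers of 100 ReLU units, trained with MSE loss and
Adam at 1e-3. The window tolerates line-level amplitude noise; a single
sample would be noisier. The held-out MSE is reported on the normalised
scale alongside the RMSE in mm, since the scale of the reference value
for this error is not stated.

Gated reconstruction removes lines with more than 20 mm of predicted
displacement, or lines inside labelled cough windows (the simulator's
truth labels, or windows from the amplitude/derivative outlier
detector), and applies the density-compensated adjoint. Density
compensation is the analytic ramp |k| with a half-cell disc weight at
DC and per-spoke angular Voronoi widths (golden-angle directions are not
exactly uniform, and gated subsets even less so — Voronoi weights adapt
automatically). The gated subset keeps its nominal spoke count only in
metadata; weights always reflect the retained spokes.

## Ultrasound pipeline

Complex A-mode reconstruction is quadrature demodulation at the pulse
frequency followed by a 4th-order Butterworth low-pass (0.8 of the pulse
frequency) applied forward–backward, giving the analytic signal whose
magnitude is the echo envelope. Normalisation divides by the global
maximum, so values lie in [0, 1].

The bladder-area ground truth thresholds the calibration image stack
with one global Otsu threshold (computed from the pooled histogram; a
global threshold is what makes 3D connectivity across (x, y, t)
meaningful), labels per-frame 2D components, links them across frames by
overlap into 3D components, and keeps the largest; per-frame area is
pixel count × pixel area. Frames where the component vanishes are
recorded as area 0 with a QC flag.

The area predictor is a 1D CNN — four convolution blocks (kernel 9,
stride 2, channels 8→64, ReLU) over the profile resampled to 384
samples, a flatten, a 64-unit hidden layer, and a linear output that
also receives the raw input profile through a direct skip path. Two
choices matter here. A global-average-pooling head was rejected because
it is translation-invariant, and depth *position* is exactly the signal
(wall separation ↔ area). The skip path means the network contains a
plain linear readout of the profile as a special case, which a ridge
oracle shows is already close to the achievable error; the convolutional
features then supply nonlinear corrections, and optimisation does not
have to rediscover the linear solution through the trunk. Training uses
AdamW (lr 1e-4, decoupled weight decay 5e-4), the Huber loss on
z-scored areas, batch 64, and early stopping (patience 80) on a
contiguous validation split. Error floors: the Otsu ground truth
carries ≈20 mm² of rasterisation noise around the smooth geometry; part
of it is a deterministic function of the geometry and therefore
learnable, the rest bounds the achievable MAE from below.

## ToF pipeline

The respiratory waveform is the mean Z over valid pixels per frame;
invalid (overexposed) pixels are ignored frame by frame, and frames with
no valid pixels are interpolated and QC-flagged. The estimator is linear
in the surface, so doubling the programmed surface excursion doubles the
waveform, and it is unbiased under random invalid-pixel patterns.

ROI SNR is mean/sd (sample sd) over a rectangle; pixelwise SNR maps use
a sliding 5×5 window. For comparing two maps, the two-sided independent
two-sample t-test uses pooled variance (Welch is available). One
statistical subtlety: sliding windows overlap, so neighbouring map
pixels are strongly correlated, and a t-test over all ROI pixels is
badly anti-conservative. The test populations are therefore subsampled
at window stride inside the ROI, which restores the nominal test level
(verified by a Monte-Carlo check in the test suite).

## Scanner-less fusion

SDR demodulation FFTs non-overlapping 5120-sample blocks (at 3 MHz:
585.94 blocks/s), reads the magnitude at the bin nearest the tone, and
applies a 9-point median filter; a trailing partial block is dropped.
Block overlap is configurable but off by default since the processing
description implies consecutive groups. For long desk-scale runs the
stream can be generated at a decimated rate with the block size scaled
to keep the same block rate.

OCM depth-band displacement maximises the normalised cross-correlation
of each column's band profile against a reference column over a lag
window, with parabolic sub-sample refinement; positive displacement
means interfaces moving away from the transducer. Profiles are decimated
4× in depth before correlation — the envelope is an order of magnitude
wider than one RF sample, so this costs no information — and the default
lag window (80 decimated samples ≈ 12 mm) covers cough-scale shifts.
Columns whose correlation peak is below 0.2 are flagged low-confidence.

`align_streams()` interpolates all curves onto a uniform grid over their
common support; `correlate_sensors()` reports the Pearson matrix
(constant curves give NA) and per-sensor event windows from a robust
(median/MAD) outlier rule on amplitude and first derivative (threshold
4, windows merged below 0.6 s gaps). On the standard 25 s protocol (a
deep breath and coughs in the first 4 s, then normal breathing) the tone
and ToF curves correlate above 0.9 and the two ultrasound bands
anticorrelate, reproducing the anti-phase behaviour of interfaces moving
in opposite directions relative to the transducer. The sign of the tone
amplitude modulation is arbitrary in reality (it depends on coil
loading geometry); the fusion default uses a negative coupling so that
tone amplitude and camera distance move together.

## Containers, configuration, reproducibility

Runs live in a single-file container with groups `/kspace`, `/amode`,
`/tof`, `/iq`, `/truth` (schema-validated on read; unknown groups warn,
missing datasets error with the missing path). Curves export to CSV,
reports to JSON, reconstructions to NIfTI. `run_pipeline()` executes the
six stages (`simulate`, `pt-calibrate`, `pt-correct`, `ocm-train`,
`tof-extract`, `fusion-run`) from a YAML `run_config` that rejects
unknown keys; every stage appends a log entry with the config hash and
seed. Every simulator and training function takes an explicit seed and
restores the caller's RNG state; identical seed and configuration give
bit-identical outputs on a single BLAS thread.

## Problem sizes and limitations

The shipped experiments use 3 abdominal subjects × ~176 calibration
frames for segmentation; a 15–24 s radial acquisition (4–7×10³ spokes)
for tone calibration; and, for the bladder model, 24 s pelvic runs at
100–200 A-mode columns/s — a single-subject run with a held-out time
segment, and a 4-subject run with one whole subject held out. The
cross-subject subjects share the anatomical template and differ in
breathing pattern, event schedule, speckle realisation and noise: with
only three training subjects, anatomical scale variation lets the
network key on subject-specific static speckle as an identity feature
and mis-transfer each subject's baseline area (even a linear oracle
does), so scale variation is deliberately not part of the default
cross-subject protocol and is listed as a limitation below. These sizes
keep each experiment in the minutes range on one CPU core.

Within a run the predictor reaches a frame-level MAE near the Otsu
ground truth's own quantisation floor. Across subjects the transfer gap
is larger: part of the speckle-zone response remains subject-specific,
and the unseen-subject MAE stays a factor of a few above the
within-run value at this cohort size. Stationary-clutter removal (per
subject mean A-line subtraction) was evaluated as a remedy and
rejected: it removes exactly the absolute wall-geometry information the
area readout relies on.

What passing these synthetic experiments shows is that the processing
chains are internally consistent: the implemented extraction, gating,
reconstruction, segmentation and regression recover what the simulator
put in, at error levels comparable to the reference metrics. What they
cannot show is robustness to everything the phantom does not model:
bSSFP banding and tissue contrast, coil sensitivity profiles and
multi-channel tone combination, acoustic speckle statistics and probe
coupling, camera exposure artifacts, clock skew between real devices,
and inter-subject anatomical variability beyond scaled geometry. The
motion-gated reconstruction is deliberately simple (line rejection plus
adjoint NUFFT); soft gating and motion-resolved iterative
reconstructions are out of scope.
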
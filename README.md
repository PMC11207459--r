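# mrmotion

Respiratory and organ motion corrupt MRI exams and complicate
position-sensitive treatments such as radiation therapy. `mrmotion` is an
R package for studying three complementary MRI-compatible motion sensors
and their processing chains at desk scale, entirely on synthetic data
with known ground truth:

1. **Pilot-Tone (PT)** — an RF tone transmitted near the bore at an
   offset outside the imaging band. Body motion modulates the amplitude
   the MR coils receive. The package extracts the tone from raw radial
   k-space (spectral peak per readout line), calibrates a fully
   connected network (5 × 100 ReLU units) mapping tone amplitude to
   image-derived liver displacement, and performs motion-gated
   density-compensated NUFFT reconstruction (removing k-space lines with
   more than 20 mm of predicted motion, or lines acquired during
   coughs).
2. **A-mode ultrasound (OCM sensor)** — a single-element 1 MHz
   transducer whose echo train encodes organ configuration through
   depth. A 1D convolutional network predicts the mid-sagittal bladder
   area (ground truth: Otsu threshold + 3D connected components on fast
   calibration images) from one normalised depth profile.
3. **Time-of-Flight depth camera** — per-pixel distance to the abdominal
   surface at 5 frames/s; the respiratory waveform is the mean Z over
   valid pixels, and ROI-based SNR comparison with a pooled two-sample
   t-test quantifies interference effects.

A scanner-less mode processes all three simultaneously: software-defined
radio IQ demodulation of the tone (FFT over 5120-sample blocks, 9-point
median filter), depth-band displacement tracking by normalised
cross-correlation (0–3.3 cm and 3.3–6.6 cm bands), and common-timeline
alignment with cross-sensor correlation and aberrant-motion event
detection.

All raw data come from a parametric breathing phantom
(`make_breathing_phantom()`): seeded trajectories with asymmetric
breathing cycles, deep breaths, coughs, and pelvic-floor contractions;
anti-aliased 2D anatomy rendering; exact non-uniform Fourier sampling of
golden-angle radial spokes; Gabor-pulse A-mode echoes over moving
reflectors and tissue speckle; depth frames with invalid pixels; and IQ
streams. The small neural networks (2D U-Net, FCN, 1D CNN) are trained
with the package's own single-precision conv/backprop kernels
(Rcpp/Armadillo) using Adam/AdamW, Dice/MSE/Huber losses.

## Worked example: Pilot-Tone gating

```r
library(mrmotion)

ph <- make_breathing_phantom(phantom_config(duration_s = 8,
                                            cough_times = c(5.0, 5.8)),
                             seed = 5)
ks <- simulate_radial_kspace(ph, seq_params_radial(n_spokes = 2000),
                             noise_sd = 0.2)
tr <- ph$trajectory
disp <- displacement_curve(tr$times,
                           tr$resp_displacement - min(tr$resp_displacement))
ref <- phantom_image(ph, tr$times[which.min(tr$resp_displacement)])

nrmse(reconstruct_nufft(ks), ref)
#> [1] 0.1609766
g20 <- gate_kspace(ks, disp, threshold_mm = 20)
attr(g20, "retained_fraction")
#> [1] 0.7985
nrmse(reconstruct_nufft(g20), ref)
#> [1] 0.121422
nrmse(reconstruct_nufft(gate_kspace(ks, events = event_intervals(ph, "cough"))), ref)
#> [1] 0.1417269
```

Discarding the ~20% of spokes acquired beyond 20 mm of motion (deep
breath) lowers the reconstruction error against the motion-free
reference from 0.161 to 0.121 NRMSE; removing only the cough windows
gives 0.142 with 88% of the data retained.

The full pipelines (simulate → pt-calibrate → pt-correct → ocm-train →
tof-extract → fusion-run) run via `run_pipeline()` on a YAML
configuration, or from a shell through `inst/cli/mrmotion.R`. See the
vignette (`vignettes/motion-sensors.Rmd`) for the models, parameter
choices and limitations.

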
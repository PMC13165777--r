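# hrvideo

Contactless heart-rate estimation from colour face video (remote
photoplethysmography, rPPG) in R.

Each cardiac cycle changes the blood volume in facial skin, which modulates
diffuse light reflectance by a fraction of a percent. `hrvideo` recovers that
modulation from ordinary video and turns it into a heart-rate (HR) estimate
per 15 s segment, for researchers building or validating camera-based vital
sign monitoring. The pipeline is a hybrid of signal processing and machine
learning:

1. **Stabilization** — each frame is mapped into a canonical face coordinate
   system by a least-squares similarity fit of 478 facial landmarks,
   `p' = s R(θ) p + t`, with each parameter smoothed by an adaptive
   exponential moving average `p̂ₜ = (1 − α) p̂ₜ₋₁ + α pₜ`
   (α = 0.05, ramping to 0.8 while the rotation error exceeds 0.05 rad),
   followed by Lucas–Kanade optical-flow removal of residual horizontal
   drift.
2. **ROI selection** — the canonical face is tessellated into small
   triangles; triangles whose centroids fall in the forehead/cheek polygons
   are kept, then 2-means clustering of their temporal-mean chrominance
   (U, V) discards poorly lit regions (the cluster nearest the well-lit skin
   reference U ≈ 30, V ≈ 45 survives).
3. **Eulerian video magnification** — the level-3 Gaussian-pyramid band in
   YIQ is temporally band-passed to 0.8–3.0 Hz over the ROI, amplified by
   α = 50, upsampled and recombined with a per-pixel saturation-safe factor
   k = min over channels of (1 − I)/ΔI (or −I/ΔI), then quantized to 8 bits.
4. **Trace cleaning** — per-triangle mean-green traces over 30 s episodes
   (15 s overlap) are gated by the modified z-score
   `z = 0.6745 (x − median)/MAD` (outlier ratio > 0.4 discards a trace), and
   a Gaussian notch `H(f) = 1 − 0.7 exp(−(f − 2f₀)²/2σ²)` (σ = 0.1 Hz)
   suppresses the first harmonic, re-adding the removed magnitude in phase
   at the fundamental.
5. **Source separation** — sliding-window PCA (width
   `min(max(⌊M/3⌋, 5), M)`, stride 3, 2 PCs per window), correlation-based
   retention (|r| > 0.5 to the most representative component), global PCA
   capped at 10 modes, and SOBI (joint diagonalization of lagged
   covariances, lags 1–20).
6. **Source selection and HR** — each SOBI component is featurized by a
   wavelet-scattering transform of the signal and its autocorrelation and
   classified by a gradient-boosted tree model (decision threshold 0.35),
   with a fallback selecting the first component when it carries > 75 % of
   the back-projected power, and a deliberate *null* estimate when neither
   fires. Selected components are back-projected, phase-aligned, averaged,
   linked across episodes through the first PC of the overlapping 15 s
   tails, and the HR is 60 × the spectral peak in 0.8–3 Hz.

A fully ground-truthed synthetic scene generator (face-like ellipse with a
known pulsatile colour signature, smooth head motion, a shadowed cheek,
sensor noise and a paired 256 Hz reference PPG) makes every stage testable
without any dataset or landmark model; external 478-point detectors plug in
through a provider interface.

## Worked example

```r
library(hrvideo)

## train the source selector on a labelled synthetic corpus
corpus   <- make_source_corpus(seed = 11)
selector <- train_selector(corpus$features, corpus$labels, corpus$subjects)
selector
#> source_selector (gradient-boosted trees)
#>   LOSOCV @ 0.35: acc 0.886, precision 0.942, recall 0.700, F1 0.803

## a 60 s synthetic scene at 72 bpm with motion, shadow and noise
scene  <- make_scene(scene_config(duration_s = 60, hr_bpm = 72, seed = 21))
result <- run_pipeline(scene$video, landmark_provider_synthetic(scene$truth),
                       selector = selector)
result$estimates
#>   segment_start_s   hr_bpm       mode peak_hz
#> 1              15 71.92383 classifier 1.19873
#> 2              30 71.92383 classifier 1.19873
#> 3              45 71.92383 classifier 1.19873

evaluate_against_reference(result, scene$truth$ppg)$report
#> evaluation_report (n = 3, null = 0)
#>   MAE 0.05 bpm | RMSE 0.08 bpm | MER 0.07% | PCC NaN
#>   bias -0.05 bpm, SD 0.08 bpm, LoA [-0.21, 0.12] bpm
```

Each row is one 15 s segment: the classifier found a physiological SOBI
component in every episode and the spectral peak at 1.199 Hz reads back as
71.9 bpm against the injected 72 bpm (the 0.08 bpm offset is the zero-padded
FFT grid). The evaluation pairs the estimates with the reference-PPG HR on
the same segment grid; here all three estimates are constant and essentially
exact, so the error statistics are ~0 and the Pearson correlation is
undefined (reported as NaN).

A thin command-line wrapper over the same functions is installed at
`inst/cli/hrvideo.R` (`process`, `synth`, `train`, `eval` subcommands).

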
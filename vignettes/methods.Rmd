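---
title: "Heart-rate estimation from face video: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate estimation from face video: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hrvideo` estimates heart rate from the minute colour fluctuations that
cardiac blood-volume changes imprint on facial skin. This vignette is the
package's own account of the method: the model behind each stage, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The signal and its enemies

The usable signal is a quasi-periodic modulation of diffuse skin
reflectance at the cardiac fundamental (0.8–3 Hz, i.e. 48–180 bpm), with an
amplitude of order 0.1–2 % of the skin intensity, strongest in the green
channel. Everything else is an enemy: rigid head motion couples the spatial
image gradient into every pixel's time series, uneven illumination makes
some facial regions uninformative, sensor noise and 8-bit quantization sit
at or above the signal amplitude, and the first harmonic of the pulse can
exceed the fundamental and flip a spectral-peak reader to double the true
rate. The pipeline is a sequence of stages each aimed at one of these.

## Stabilization

Per frame, a 4-degree-of-freedom similarity transform (translation,
in-plane rotation, isotropic scale) is fitted by closed-form least squares
(Procrustes) from the 478 detected landmarks to a canonical reference face,
itself the mean of the first 15 reliably detected frames. A full affine fit
would admit shear, which the parameter decomposition used for smoothing
could not represent exactly; restricting to a similarity makes
decompose-reconstruct an identity, which the tests assert to 1e-12.

Each parameter is smoothed with an exponential moving average. The baseline
factor `alpha_slow = 0.05` (per frame, dimensionless) suppresses
landmark-detection jitter; when the rotation observation departs from the
smoothed rotation by more than `theta_threshold = 0.05` rad the filter
enters a correction phase, raising alpha by `ramp = 0.15` per frame up to
`alpha_fast = 0.8`, and resets to the baseline on the first frame back
under the threshold. The published description leaves the ramp schedule and
the "error subsided" criterion open; the linear ramp with immediate reset
is the simplest monotone choice and settles in about five frames, and both
knobs are configurable.

Warping uses bilinear interpolation with replicate borders (a constant
border colour would leak darkness into edge triangles). The warp follows
the sampling convention `out(q) = frame(A q + t)` — the parameters define
the map from output to input coordinates — so the stabilizer passes the
inverse of the smoothed current-to-canonical transform. A second stage
tracks the leftmost and rightmost face-boundary landmarks between
consecutive stabilized frames with iterative Lucas–Kanade optical flow
(15 × 15 window, up to 10 Gauss–Newton steps) and removes their mean
horizontal displacement from the canonical x positions as a pure
translation; the published method names "left and right facial boundaries"
without indices, so the template's extremal landmarks are the default and
the indices are configurable.

An EMA-based corrector removes drift and slow wander but cannot cancel
frame-to-frame white motion, which is why the second, unsmoothed
translational stage exists for the horizontal axis. Correspondingly, the
synthetic scenes model head motion as smooth band-limited wander (two
incommensurate sinusoids below 0.15 Hz, scaled to the configured SD) plus a
small iid landmark-noise floor — physical head motion is slow, and a
frame-iid rigid-motion model would be neither realistic nor correctable by
any causal smoother.

Residual jitter is quantified as in the stabilization literature: frames
whose inter-frame landmark speed exceeds the mean plus one SD are the
high-motion set; positional jitter is the spatial standard deviation
(population form, `sqrt(var_x + var_y)`) of a cheek landmark over that set
and rotational jitter the SD of the rotation angle. With no high-motion
frames the whole trajectory is used and flagged.

## ROI tessellation and chrominance filtering

The canonical face is tessellated by a fixed triangulation shipped with the
package. The 478-point layout and its triangles are generated
deterministically in code (a regular grid clipped to an elliptical face
outline, grid cells split into triangles) rather than stored as a static
file; the anatomical forehead/cheek polygons are landmark-index loops over
that layout and can be overridden in configuration. Centroid-in-polygon
uses an even-odd test with boundaries counting as inside.

Light-quality filtering computes each candidate triangle's temporal-mean
RGB over the original (non-magnified) stabilized video, converts to
zero-centred BT.601 YUV on the [0, 255] scale (`U = 0.492 (B − Y)`,
`V = 0.877 (R − Y)`), and runs 2-means on the (U, V) pairs with 10
restarts under a fixed, restored seed. The cluster whose centroid is
nearest the well-lit skin reference `(U, V) = (30, 45)` is retained. The
reference value is configurable and not critical — the clustering adapts to
the scene — and two guard rails apply: fewer than two candidates skips
clustering (retain all, warn), and exactly equidistant centroids retain the
union, since dropping signal channels is the costlier error.

## Eulerian video magnification

Frames are converted to YIQ (NTSC matrix), reduced three
blur-and-decimate steps (5-tap binomial kernel [1,4,6,4,1]/16, replicate
borders; level indexing is 0-based from full resolution, so level 3 is 1/8
scale), and each masked band pixel's time series is filtered by an ideal
FFT bandpass over 0.8–3.0 Hz — zero-phase, unit passband gain, which makes
the stage's gain exactly the magnification factor and testable as such. The
filtered band is multiplied by `alpha = 50` in all three channels,
upsampled with Catmull–Rom cubic interpolation, re-masked at full
resolution (so non-ROI pixels stay bit-identical after quantization), and
added to the original YIQ frame.

Saturation is handled per pixel: with `dI` the RGB delta, the largest
`k in [0, 1]` is found with `k <= (1 - I)/dI` for positive and
`k <= -I/dI` for negative deltas, the minimum across channels applied, and
the result clipped and quantized to 8 bits. Traces are extracted after
quantization, following the stated order of the procedure; the quantization
step is part of what the downstream stages must survive.

Magnification runs per 30 s episode rather than over the whole video so
memory stays bounded; with the ideal filter applied per episode the two
formulations agree inside the episode.

## Trace cleaning

Episodes are `M × T` matrices of per-triangle mean-green traces, ordered
spatially — forehead rows first, then left and right cheek, each row left
to right — because the sliding-window PCA groups *adjacent* traces and the
source never fixes an ordering.

Gating uses the modified z-score `z = 0.6745 (x − median)/MAD` with the
unscaled MAD; `MAD = 0` (a constant trace) defines all scores as zero. The
outlier ratio divides the outlier count by outliers plus detected peaks,
and traces above 0.4 (strictly) are discarded. The peak detector is
unspecified in the source; the package uses local maxima with prominence at
least half the trace SD and minimum spacing `fs / 3 Hz` samples — the
tightest spacing a cardiac signal at the band's upper edge can produce —
and both knobs are configurable. A 0/0 ratio is defined as 0.

Harmonic suppression first decides whether the in-band spectral peak is a
harmonic: if any bin within one FFT bin of half the peak frequency carries
more than 40 % of the peak magnitude, that half-frequency bin is the
fundamental. The Gaussian notch `H(f) = 1 − 0.7 exp(−(f − 2f₀)²/(2·0.1²))`
is applied symmetrically at ±2f₀ (required for a real output), and the
magnitude it removes is re-added at the fundamental bin in phase. The
removed magnitude is summed over *all* positive-frequency bins rather than
a 3-sigma window: the Gaussian notch has tails, and only the window-free
definition makes the conservation of the total spectral magnitude exact
(the tests assert it to 1e-9 on two-tone signals) instead of approximate.

Time-point cleanup zeroes samples more than `tau = 4` SDs from the mean and
re-applies the 0.8–3 Hz bandpass to remove the discontinuities zeroing
introduces. Harmonic suppression runs both per trace before separation and
per SOBI component after it, as the staged description implies.

## Source separation

The window plan uses `width = min(max(floor(M/3), 5), M)` with stride 3;
the final window is shifted left to end at trace M and duplicate starts are
dropped so no window contributes identical component copies to the
correlation vote (floor-vs-round for M/3 is unspecified in the source;
floor is the documented choice here). Traces are z-scored before every PCA
stage so high-amplitude traces cannot dominate; each window yields its top
two principal-component time courses with loadings retained.

Correlation selection computes the pairwise |Pearson r| matrix, calls the
component with the highest mean absolute correlation the representative,
and keeps components strictly above 0.5 against it. Global PCA then caps
the set at 10 orthogonal modes.

SOBI whitens the capped set and jointly diagonalizes symmetrized lagged
covariance matrices at lags 1–20 samples (1 s at 20 FPS — enough to span a
full cardiac period anywhere in the band) by Jacobi rotation sweeps
(closed-form 2 × 2 rotations from the principal eigenvector of the pair's
criterion matrix; rotation tolerance 1e-8, at most 100 sweeps;
non-convergence returns the best iterate with a warning, and the
off-diagonal criterion is asserted non-increasing). Unmixing and mixing
operators are stored at every stage, so selected components can be
back-projected exactly: SOBI mixing, global-PCA loadings, then per-window
loadings with overlapping windows averaged per trace, undoing each
z-scoring.

## Source selection

Each cleaned SOBI component is featurized by a time-averaged wavelet
scattering transform — Gabor filter bank with J = 6 octaves and Q = 8
first-order wavelets per octave (one per octave at second order), orders
0–2 — applied to both the z-scored component and its biased autocorrelation
(lags 0..T/2, unit at lag 0). The configuration covers 0.3–10 Hz structure
at 20 Hz sampling on 600-sample episodes; the source names no parameters,
so these are package choices, and the coefficient layout is fixed given
(J, Q), making vectors comparable across runs.

The classifier is a gradient-boosted decision-tree model (binary logistic
objective, 200 trees, depth ≤ 6, learning rate 0.05, class-weighted for
the pulse/noise imbalance, single-threaded and seeded for reproducibility).
Leave-one-subject-out cross-validation is the validation harness — each
subject's sources are scored by a model that never saw that subject — and
deployment uses one fixed model trained on everything. Components with
probability strictly above 0.35 are selected; if none pass, the first SOBI
component is selected alone when its power ratio (its mixing column's
squared norm over the total, components having unit variance) exceeds
0.75; otherwise the episode deliberately yields a *null* estimate. A null
is a feature, not a failure: in continuous monitoring a dropped 15 s
segment is far cheaper than a confidently wrong rate.

Training labels for synthetic corpora come from `auto_annotate`: a source
is physiological when its absolute correlation with the reference reaches
0.7 and the FFT peaks agree within one bin.

## Reconstruction, linking and the rate readout

Back-projected traces are band-passed, lag-aligned to the first trace by
maximizing cross-correlation over ±1 s (inter-region pulse-transit delays
are far below a second), sign-corrected to positive correlation and
averaged. Consecutive episodes share 15 s; the representative tails are
stacked, z-scored, and reduced to their first principal component, its sign
set by positive correlation with the current tail (the source is silent on
the sign; any deterministic convention works because the spectral readout
is sign-blind). The heart rate is 60 times the spectral argmax in
0.8–3 Hz.

Fifteen seconds at 20 Hz gives native 4 bpm bins, too coarse for
single-bpm-level errors, so the trace is zero-padded to 8192 samples
(~0.15 bpm grid) before the FFT; padding is configurable and can be
disabled. Estimates are reported per 15 s boundary from the first episode's
end onward (a 60 s video yields three).

## Reference processing

The 256 Hz reference PPG is mean-removed, band-passed with a zero-phase
third-order Butterworth over 0.8–3 Hz, linearly resampled to 20 Hz (safe:
the signal is band-limited far below the new Nyquist), detrended by the
smoothness-priors method (trend = `(I + λ² D₂ᵀD₂)⁻¹ x`, sparse banded
solve) with `lambda = 120`, normalized by its Hilbert analytic envelope
(floored at 1e-6 of the envelope median; a degenerate, near-zero envelope
flags the reference as unusable rather than dividing by noise), segmented
into 15 s segments and read out by the same padded FFT peak.

One ordering decision deserves its own paragraph. The smoothness-priors
trend filter has response `1/(1 + λ²(2 sin(ω/2))⁴)`, so its cutoff scales
with the sampling rate: `lambda = 120` cuts near 0.29 Hz at 20 Hz — exactly
what baseline removal below a 0.8 Hz band needs — but near 3.7 Hz at
256 Hz, which would remove the cardiac band itself. The printed
regularization value is therefore only coherent at the resampled rate, and
the package detrends after resampling. Every printed parameter value is
kept; only the stage order moves.

Agreement metrics are MAE, RMSE, MER (mean |error| as a percentage of the
reference), Pearson correlation, and Bland–Altman bias with
`bias ± 1.96 SD` limits of agreement; null estimates are excluded pairwise
and counted. Zero references are skipped in MER with a warning and constant
vectors make the correlation NaN with a notice.

## The synthetic scene generator

`make_scene` renders a skin-toned ellipse on a textured background, places
the 478-landmark template on it, and injects: a pulse
`sin(2π f₀ t) + 0.3 sin(4π f₀ t + φ)` applied as `ΔG = −a·p(t)`,
`ΔR = −0.5 a·p(t)` on skin pixels (blood absorption lowers reflectance,
green most strongly; default amplitude a = 0.01 in [0, 1] intensity units,
mid-range of realistic rPPG contrast); smooth rigid motion (0.03 Hz drift
of 2 px amplitude, wander scaled to 1.5 px and 0.01 rad SD, optional step
rotation for exercising the correction phase); a shadowed right cheek
(luminance factors (0.48, 0.72, 0.70) per channel — reduced luminance with
a cooler, desaturated cast, as under skylight fill — chosen so the shadow's
chrominance moves away from the well-lit reference); iid Gaussian pixel
noise (SD 0.01); 0.15 px landmark observation noise; and a paired 256 Hz
reference PPG built from two-Gaussian beats (systolic bump at 15 % of the
period, width 7 %; diastolic at 45 %, width 12 %, amplitude 0.45) with
baseline drift and noise. Everything is seed-deterministic and the ground
truth (landmarks, transforms, pulse, shadowed-triangle ids, PPG) is
returned alongside the video.

What the generator does **not** emulate: photorealistic skin texture and
specular highlights, out-of-plane head rotation, video-codec compression
artifacts, expression and eye-blink deformation, and detector-specific
landmark failure modes. Passing the synthetic suite therefore demonstrates
the pipeline's signal path — geometry, filtering, separation, selection,
bookkeeping — not robustness to every property of real recordings;
conclusions about real-world accuracy require real video with reference
physiology.

`make_mixture` exercises the separation stages alone: a quasi-periodic
pulse (fundamental, 0.3-amplitude second harmonic, slow frequency wander)
mixed with AR(1) and white noise sources through a random full-rank matrix
whose pulse column is scaled to a per-channel SNR.

## Problem sizes and budgets

The shipped tests run synthetic scenes at 160 × 120 pixels and 20 FPS —
30 s for unit checks, five 60 s scenes (50–150 bpm) for the end-to-end
recovery check — a scale at which a full pipeline pass takes about a minute
per scene on one CPU core and the whole suite stays within a
quarter-hour. These sizes are package choices balancing coverage against
runtime; nothing in the method depends on them, and full-resolution video
only scales the per-frame image operations.

## Known limitations

- Only in-plane rigid motion is corrected; out-of-plane pose change is
  explicitly out of scope.
- One face per video; the first detected face wins.
- The shipped classifier-training corpus is synthetic; on real data the
  selector should be retrained on annotated sources from the target
  recording setup (the power-ratio fallback and null mode still guard an
  untrained or mismatched model).
- Beat-to-beat intervals and heart-rate variability are not computed; the
  spectral readout gives one rate per 15 s segment.
- Video I/O reads directories of PNG frames (and in-memory arrays);
  container decoding (AVI/MP4) is delegated to external tooling such as
  ffmpeg extracting frames.
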
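---
title: "Complex-valued phase-amplitude coupling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex-valued phase-amplitude coupling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the complex-valued phase-amplitude coupling (CV-PAC) feature, its
surrogate screening, the complex-valued convolutional network (CV-CNN)
classifier, the synthetic-signal generator that stands in for patient
recordings, and the channel-level evaluation. It documents the modelling
assumptions, every tunable that matters, and the numerical and design
choices made where the method definition was genuinely open.

## 1. The CV-PAC feature

Phase-amplitude coupling (PAC) is the dependence of a fast oscillation's
amplitude envelope on the phase of a slow oscillation. The package
quantifies it with the Kullback-Leibler modulation index. For a
frequency pair $(f_P, f_A)$:

1. The instantaneous phase $\Phi_{f_P}(t)$ and amplitude $A_{f_A}(t)$
   are extracted by continuous wavelet transform (complex Morlet, below).
2. Phases are assigned to $N = 18$ equal bins tiling $[-\pi, \pi)$, and
   the mean amplitude per bin is normalized to a distribution
   $P(j) = \langle A_{f_A}\rangle_j \big/ \sum_k \langle A_{f_A}\rangle_k$.
3. The coupling strength is the KL distance to the uniform distribution
   $U(j) = 1/N$, normalized to $[0,1]$:
   $S = D_{KL}(P, U) / \log N$, with $D_{KL} = \sum_j P(j)\log(P(j)/U(j))$
   and $0\log 0 := 0$. $S = 0$ iff $P$ is uniform and $S = 1$ iff $P$ is
   one-hot. The ratio is independent of the logarithm base; natural log
   is used internally.
4. The coupled phase $\psi$ is the center angle of the arg-max bin of
   $P$, reported in $[-\pi,\pi)$; ties break toward the lowest bin index.
5. The pixel is the complex number $C = S\cos\psi + iS\sin\psi$, so the
   comodulogram carries strength as modulus and phase as argument in one
   image.

The comodulogram grid is $10\times10$: phase frequencies 1-10 Hz and
amplitude frequencies 30-160 Hz, both split into 10 intervals with
log-equal edges; each interval is represented by the geometric mean of
its edges.

**Phase-bin convention.** An equivalent formulation writes the coupled
phase as $\text{argmax}_j P(j)\cdot \pi/9$, which lands in $(0, 2\pi]$.
Comodulogram phase displays in this field use $[-\pi, \pi]$, and the
complex argument is canonically reported there, so this package defines
the bins to tile $[-\pi,\pi)$ with centers $-\pi + (j-\tfrac12)\pi/9$ and
reports $\psi$ as the arg-max bin **center**. Any workflow mixing this
package with one using the $(0,2\pi]$ convention must rotate phases
accordingly.

**Empty phase bins.** A 10 s window at a 1 Hz phase frequency sees only
~10 cycles; a phase bin can end up empty in pathological cases. The
default treats an empty bin's mean amplitude as 0 and flags the image
(`empty_bin` in the provenance); a strict mode rejects the window
instead. Flagged images are rare with the default grid and window length
but should be filtered when they matter.

## 2. Wavelet choice

The method definition names continuous wavelet transform but not the
wavelet or the scale scheme. The package uses an analytic complex Morlet
filter applied in the frequency domain: the spectrum is multiplied by a
positive-frequency Gaussian centered on the target frequency with
standard deviation $\sigma_f = f/n_{cycles}$, giving an analytic band
signal whose modulus/argument are the envelope and phase. One
coefficient series is computed per interval center frequency (no
averaging across scales within an interval).

`n_cycles` controls the time-frequency trade-off. The default is 7:
with the log-spaced grids the response at a neighbouring interval center
is then $\exp(-(\Delta f)^2/2\sigma_f^2) \approx 0.19$ on the
low-frequency axis and $0.44$ on the high-frequency axis — under the
50% overlap target on both axes — while a 1 Hz wavelet still fits
comfortably in a padded 10 s window.

**Edge handling.** Windows are cut before the transform; to control
wavelet edge effects every window is extracted with 2 s of real context
per side where the record allows (zero-padded at record boundaries), the
transform runs on the padded series, and the pad samples are excluded
from the phase binning.

## 3. Surrogate screening (ST-CV-PAC)

Each pixel is screened against a null in which the phase-amplitude
alignment is destroyed: the amplitude series is shuffled against the
phase series 100 times per low-frequency interval, the strength is
recomputed each time, and the pixel is zeroed unless its observed
strength is at least the smallest of the top $\lfloor\alpha
n\rfloor$ shuffled strengths (the "top 5%" block at $\alpha = .05$,
$n = 100$). Under the null this retains a pixel with probability
$\lfloor\alpha n\rfloor/(n+1) = 5/101 \approx 4.95\%$.

**Why circular shifts.** "Shuffling" could mean a full random
permutation or a circular time shift. Wavelet envelopes are strongly
autocorrelated, and a full permutation destroys that autocorrelation in
the surrogates while the observed statistic keeps it — the permutation
null is therefore badly anti-conservative here (on pure white noise it
retains the large majority of pixels rather than 5%). A random circular
shift of the amplitude-versus-phase alignment preserves the
autocorrelation of both series and empirically retains ~5% of
noise-only pixels, matching the construction. The default is therefore
`method = "shift"`, with offsets drawn uniformly from $\{1, \dots,
n_{samples}-1\}$; restricting offsets away from zero was measured to
*inflate* retention (it removes the conservative near-original
surrogates) and is not done. Full permutation remains available as
`method = "permute"` for comparison.

One caveat: at the lowest phase frequencies the wavelet coherence time
(~7 cycles, i.e. ~7 s at 1 Hz) is comparable to a 10 s window, so
circular shifts cannot fully decorrelate those columns; the measured
overall calibration stays within the binomial band, but per-column rates
are noisier at 1-2 Hz.

## 4. The CV-CNN classifier

The classifier follows the complex-network recipe: three complex-valued
convolutional layers, each `conv -> complex batch norm -> split ReLU`,
then four complex fully connected layers, with real logits read out of
the final width-2 complex activation. Complex convolution and linear
layers apply the complex product rule to real/imaginary weight and
feature pairs; split ReLU rectifies the parts independently.

Training recipe (defaults): 800 epochs, batch size 128, plain SGD at
learning rate .0025 halved at every multiple of 250 epochs,
cross-entropy loss, dropout .2 on the first fully connected layer (one
mask zeroes both parts of an activation jointly), and L2 weight decay
$\lambda = .004$ applied to convolutional weights only (implemented as
`grad += lambda * w`, i.e. the penalty $\tfrac\lambda2\|w\|^2$).
Training is deterministic given the config seed. All gradients are
computed analytically in the real/imaginary parameterization and are
verified against numerical differentiation in the test suite.

Choices the recipe leaves open, and what this package does:

* **Channel counts / kernel sizes** are not part of the recipe.
  Defaults for $10\times10$ inputs: three $3\times3$ size-preserving
  layers with 16/32/64 complex channels and fully connected widths
  128/64/32/2. `cvcnn_config_small()` (8/8/16, 48/24/2, 200 epochs,
  lr .02) is the desk-scale variant used throughout the tests; both are
  fully configurable.
* **Complex batch normalization** is defined here as per-part
  standardization per channel (each part to batch mean 0 / variance 1,
  learned per-part affine, running statistics in eval mode). A
  `"whiten"` mode additionally removes the per-channel 2x2
  real-imaginary covariance by Cholesky decorrelation, with exact
  backpropagation; per-part is the default for its stability and cost.
* **Readout** of complex activations to logits is not specified.
  Default is the modulus per class, which makes the scores invariant to
  a global phase rotation of the last layer; `"real"` (real part) and
  `"affine"` (one real affine map on the concatenated parts) are
  provided.
* **Class imbalance** (ictal datasets are typically ~1:2.8
  pathological:normal) is not addressed by the recipe; the default loss
  is unweighted, with optional `class_weights`.

The real-valued baselines reuse the same engine restricted to real
arithmetic: a traditional CNN on two-layer (real/imaginary) or
strength-only images, and SVM (radial kernel, printed C/gamma grids,
default $C = 2^{18}, \gamma = 2^2$) and random forest (100 trees) on the
flattened per-part features.

## 5. The synthetic generator

Patient SEEG is not distributable, so the generator produces signals
with the statistical structure the classifier assumes. Each component
couples one slow and one fast oscillation:

$$x(t) = \cos(2\pi f_P t + \varphi_0) + \left[1 - d + d\,\tfrac{1 +
\cos(2\pi f_P t + \varphi_0 - \psi)}{2}\right]\cos(2\pi f_A t +
\theta_0) + \varepsilon(t)$$

a sinusoidal amplitude modulation locked to the slow phase, so the fast
envelope peaks where the slow phase equals the target coupled phase
$\psi$, and the modulation depth $d\in[0,1]$ controls strength ($d = 0$:
no coupling). Noise is additive white Gaussian (pink optional) with sd
0.5 relative to unit oscillation amplitude by default. The mapping from
$d$ to measured $S$ is empirical and monotone (full modulation yields
$S \approx 0.1$ at the default grid — KL modulation indices are small
numbers); no closed form is claimed.

Class structure: a window draws one component per low band (slow delta
1-2, fast delta 2-4, theta 4-8, alpha 8-10 Hz), with per-band coupled
phases drawn once per synthetic channel from a wrapped Gaussian
(sd 0.5 rad) around the class mean, and depths/frequencies redrawn per
window. Two ready-made profiles:

* `"clinical"` mimics the qualitative pattern reported for resected vs.
  non-resected tissue: class-separable phases in slow delta, fast delta
  and alpha; overlapping theta phases with stronger pathological theta
  coupling (depth 0.8 vs 0.35).
* `"phase_only"` gives both classes identical strength distributions
  everywhere (depth 0.6 ± 0.15), so only the coupled phases carry class
  information — the construction used to demonstrate that the complex
  feature beats a strength-only one.

All profile numbers are synthetic stand-ins chosen for qualitative
shape; none is a measured patient value. What the generator does *not*
emulate: seizure dynamics and spread, spikes and artifacts, non-sinusoidal
waveforms, common-reference structure beyond a shared noise term,
inter-patient variability of electrode coverage. Passing tests on this
generator show the pipeline recovers what the signal model encodes; they
are not evidence about classification accuracy on real SEEG.

The cohort generator wraps this in recording form: nine synthetic
patients with the 23 seizure durations of the reference cohort layout,
contact pairs whose anode carries the class signal under a strong shared
reference, so the bipolar montage, annotation windowing and
leave-one-patient-out machinery run end-to-end at realistic problem
sizes.

## 6. Channel-level evaluation

Window predictions are aggregated per channel as the fraction of windows
voted pathological (argmax rule; a probability-averaging variant is
provided). The ROC sweeps a threshold over observed fractions (channel
pathological iff fraction exceeds the threshold); AUC is the trapezoidal
area, identical to the Mann-Whitney rank statistic (asserted against
that oracle and against an independent ROC implementation in the
tests). The "optimal threshold" is not defined in the source method;
Youden's J is used, ties toward the lower threshold.

Leave-one-patient-out rotation trains on all other patients and scores
the held-out one; per-patient AUCs are averaged unweighted. In band
ablation, the masked band's pixels are replaced by independent
per-part Gaussian draws whose mean/variance are pooled **from the
training split only** and applied to both splits — replacement from the
full dataset would leak test statistics into training. A
circularly-symmetric replacement mode is available.

## 7. Problem sizes in the tests

The test and acceptance runs use sizes chosen to exercise every code
path at desk scale: surrogate calibration on 200 ten-second noise
windows (20,000 pixels); phase recovery over 8 target phases times 50
seeded runs; the phase-information property on 400 images per class
(40 synthetic channels per class, half held out by channel) with the
small CV-CNN for 200 epochs; and the cohort pipeline at 400 Hz with six
bipolar channels per patient and a deliberately brief training schedule,
since that criterion checks scaffolding (window counts, isolation, report
shape), not accuracy. The 400 Hz rate satisfies the >320 Hz constraint
of the 30-160 Hz amplitude axis.

## 8. Known limitations

* Single wavelet coefficient per interval; no multi-scale averaging
  within an interval. Because adjacent log-spaced intervals share Morlet
  response, a coupled pair can place its strength peak one interval off
  the simulated frequencies; the coupled phase read at the true cell is
  unaffected. Localization claims should be made at grid resolution,
  not pixel resolution.
* The surrogate null at 1-2 Hz phase frequencies is limited by window
  length (Section 3).
* The CV-CNN is a from-scratch CPU implementation intended for
  $10\times10$ comodulograms; it is not a general deep-learning
  framework and has no GPU path.
* EDF support covers continuous plain-EDF 16-bit recordings with one
  sampling rate; EDF+ annotations and discontinuous records are not
  parsed (seizure marks travel in the YAML sidecar).
* Classification performance numbers obtained on the synthetic
  generator do not transfer to patient data.
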
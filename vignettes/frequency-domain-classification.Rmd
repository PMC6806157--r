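---
title: "Frequency-domain classification of nanoparticle sensor patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain classification of nanoparticle sensor patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchfreq)
```

## The problem

Surface plasmon resonance (SPR) biosensors of the PAMONO type make
individual nanoparticle bindings — virus-like particles, polystyrene
beads — visible as small intensity steps in a stream of camera images. An
upstream detection stage proposes 48×48 pixel candidate patches; the task
of this package is the final binary decision: does a patch contain a
genuine binding (class 1) or only artifacts, vibrations and noise
(class 0)? Because bindings appear as blob-like excitations surrounded by
wave-like ripples, while typical false candidates are either smooth or
carry regular high-frequency patterns, the two classes separate well in
the frequency domain. The pipeline is deliberately light-weight — two
fixed transforms, twenty scalar features, one depth-limited decision
tree — so that it can run per-patch at camera rate on embedded hardware,
with the tree exported as plain if-else source code.

## Input contract

Patches are grayscale matrices with intensities in [0, 1]; files are
normalized on read by the dtype maximum (255 or 65535). The classifier
input is the **32×32 center crop** of the detection patch
(`center_crop()`, top-left offset `floor((H - 32)/2)`). Padding smaller
inputs is refused rather than performed: zero-padding an image before the
Fourier transform introduces interpolated spectral values whose summation
errors measurably degrade classification, whereas cropping does not.
Because the features are scale-dependent, training and inference must use
identically normalized inputs — and, more subtly, features should be
extracted on the platform where the classifier will run, since the
profile sums below accumulate thousands of floating-point terms and
platform-specific rounding can move a value across a learned threshold.

## Spectral features

For an N×N patch \(I\) (N = 32) the unnormalized 2D DFT

\[
F(l,k) = \sum_{p_x=0}^{N-1}\sum_{p_y=0}^{N-1} I(p_x,p_y)\,
e^{-2\pi i (k p_x + l p_y)/N}
\]

is computed separably (FFT on rows, then columns), the zero-frequency bin
is shifted to (N/2, N/2), and the magnitude \(|F|\) is taken — raw, with
no logarithmic compression, since the profile sums feed a scale-invariant
tree anyway. Two profiles summarize the magnitude image:

* **Radial profile** `Srad` (length 16): pixel p in the upper half-plane
  (row ≤ center row; the DC bin excluded) contributes its magnitude to
  bin `round(d(p))` of its distance to the center; bins run 1…16 and the
  few corner pixels beyond radius 16 are discarded. One half-plane
  suffices because the spectrum of a real image is conjugate-symmetric;
  using the full plane would only double every entry.
* **Angular profile** `Sang` (length 180): one line per degree,
  \(\theta_k = k\pi/180\), sampled at integer radii r = 1…16 at the
  nearest pixel \((c - \mathrm{round}(r\sin\theta_k),\;
  c + \mathrm{round}(r\cos\theta_k))\). Each (angle, radius) sample
  contributes once; neighboring lines may legitimately resample the same
  pixel. Sample coordinates are clamped into the grid: for angles within
  ~14° of the positive axis the rounded radius-16 sample would land one
  column outside a 32-pixel grid, and clamping to the edge pixel is the
  smallest consistent completion of the sampling rule (it also keeps
  every line at exactly 16 samples, so a uniform spectrum yields a
  uniform profile).

From each profile five statistics are taken — mean, maximum, 0-based
location of the maximum (first index on ties), population variance, and
max − min — giving the ten spectral features. Dominant ring frequencies
show up as bursts in `Srad`; oriented periodic patterns as bursts in
`Sang`. The discretization (180 lines × 16 samples = 2880 summands, plus
~600 radial ones) matches the scale of the summation workload the
embedded implementations of this pipeline report.

## Wavelet features

The second branch is a 3-level separable 2D Haar decomposition. Each
level transforms every row (pairwise sums and differences scaled by
\(1/\sqrt2\)), then every column of the row result — the order must be
completed within a level before recursing, otherwise a different
transform results — and decimates the image into approximation (A),
horizontal (H), vertical (V) and diagonal (D) channels; A is recursed.
Three levels over 32×32 yield 10 channels (A3 4×4; H/V/D at 4×4, 8×8,
16×16). The orthonormal \(1/\sqrt2\) scaling was chosen over plain
averaging because it makes energy conservation
\(\sum_{\text{channels}}\sum W^2 = \sum I^2\) an exact machine-precision
invariant the tests assert; any fixed rescaling would only multiply each
feature consistently and leave tree splits unchanged. Each channel
contributes its mean absolute coefficient

\[ E = \frac{1}{NM}\sum_p |W(p)| \]

(with N×M the channel's own dimensions), in the frozen canonical order
A3, H3, V3, D3, H2, V2, D2, H1, V1, D1. Blob-like excitations spread
energy into the middle-frequency detail channels; smooth negatives
concentrate it in A3.

## Classifier

Trees are grown by exact greedy CART: every axis-aligned split with a
midpoint threshold between consecutive distinct feature values is scored
by the weighted Gini impurity of the children; the best split wins, with
ties broken toward the smaller feature index and then the smaller
threshold, and `value <= threshold` routing left. Nodes split while they
are impure and above the depth cap — including zero-gain splits, without
which XOR-structured data could never be separated at depth 2. Leaves
predict their majority class, ties defaulting to 0. The default cap of
12 keeps prediction latency trivial next to feature extraction (the
benchmark harness confirms the ordering) and deeper trees have not shown
meaningful accuracy gains.

Forests are bagged trees: `n_trees` bootstrap resamples drawn from a
private RNG stream seeded by the config, all features available at every
split (no per-split feature subsampling — the contract here is
variance reduction by resampling, and determinism is easier to audit
without a second randomization). Prediction is a majority vote with
**ties returning class 0**: for a screening instrument the conservative
reading of an undecided patch is "no particle".

`export_if_else()` unrolls a tree into a C function of nested
conditionals. Thresholds are printed with `%.17g`, which round-trips IEEE
doubles exactly; the JSON model files use 17 significant digits for the
same reason. Export parity is checked by a structural interpreter that
re-parses the emitted text — not the in-memory tree — and must agree with
`predict()` on every input.

## Feature analysis

`rank_features_pca()` standardizes each feature (constant columns become
all-zero), runs PCA, and scores feature i as
\(\sum_j \mathrm{EVR}_j L_{ij}^2\) — the explained-variance-ratio-weighted
squared loadings. This is the standard operationalization of "variance a
feature accounts for"; it is frozen and documented because other readings
(top-component loading only, unstandardized covariance shares) order
features differently. Two properties are worth knowing: scores always sum
to 1, and with only two features standardization forces both scores to
0.5 — the measure is informative from three features up.

`accuracy_curve()` retrains a tree on the top-k ranked features for
k = 1…d against a single held-out split (no cross-validation; the
deployed classifier is itself trained on one split). On the synthetic
benchmark the per-family curves saturate quickly: within the ten
spectral features, accuracy at k = 6 sits within a few tenths of a point
of the full spectral set, and the wavelet curve behaves similarly. The
*mixed* 20-feature curve is slower to saturate and non-monotone: PCA
ranks by variance, not by class relevance, and can defer a decisive
spectral feature behind high-variance wavelet energies. Feature selection
for deployment should therefore be read off the per-family curves.

`extraction_plan()` turns a chosen feature subset into the minimal
dependency-closed set of pipeline stages. Its practical payoff: the
radial statistics alone need `dft2 → shift → magnitude → radial_sums`,
dropping the angular profile — by far the largest summation stage — which
the benchmark harness shows directly as a lower per-image cost.

## Synthetic data generator

The generator exists so every stage is testable without sensor data. A
positive patch is

\[
\mathrm{clamp}_{[0,1]}\!\Big(b + A e^{-d^2/2\sigma^2}
 + 0.4A\, e^{-d/\tau} \cos(2\pi d/\lambda) + \varepsilon\Big),
\]

a Gaussian blob (the binding's intensity step) with a radially decaying
ring pattern around it, Gaussian pixel noise, and a jittered center.
Defaults: background 0.5, blob amplitude 0.05–0.25, σ 2–5 px, ring at
0.4 of the blob amplitude with wavelength 4–10 px and decay length 8 px,
noise sd 0.02, jitter ±3 px, 48×48 output, balanced classes. The ring's
phase is fixed so that its crest coincides with the blob center: a free
phase would let a ring crest sit beside an attenuated core and the
patch's maximum would not reliably mark the particle position, which
both the tests and the physical picture (a bright excitation at the
binding site) expect. Negatives mix three artifact classes
(50/30/20 by default): pure noise, a low-amplitude plane sinusoid with
an integer number of cycles (sensor vibration, placed exactly on a
frequency bin so its spectral signature is sharp), and an oriented
Gaussian-profile streak.

These are invented emulations of the described appearance of real sensor
patches, not a fit to any measured distribution: real data add
non-stationary backgrounds, detector fixed-pattern noise, overlapping
and off-center particles, and temporal correlation, none of which the
generator models. Passing the synthetic benchmark therefore demonstrates
that the pipeline's machinery — features, training, export, evaluation —
works and separates this class structure; it does not certify accuracy
on sensor data, and per-platform retraining on real features remains
necessary. 8-bit PNG output is used deliberately so dataset round-trips
exercise the same quantization path as real patches.

## Numerical and design notes

* Rounding in the profile rasterization uses R's `round()` (half-to-even);
  exact .5 distances cannot occur for radial bins (distances are square
  roots of integers) and are vanishingly unlikely for angular samples.
* `round()` of the radius samples, index clamping, and the first-index
  argmax tie-break are all part of the frozen feature definition: two
  implementations must share them to produce interchangeable models.
* Metrics with zero denominators (e.g. precision with no positive
  predictions) return `NA` with a classed warning instead of 0 — accuracy
  is a reliable summary only on balanced data, and degenerate runs should
  be visible, not averaged away.
* Benchmark problem sizes: the standard synthetic benchmark used in the
  tests and the acceptance script is 4000 patches, 70/30 split, balanced
  classes — large enough for stable accuracy estimates on a single CPU,
  and the timing harness defaults to 40 batches of 25 random images
  (1000 runs). Timing output is informational; only orderings (tree ≪
  extraction, radial-only < full FFT) are ever asserted.

## Known limitations

* The spectrum-profile geometry is fixed to even N (center bin N/2) and
  tuned for N = 32; other sizes work but the 180×16 sampling density was
  chosen for 32.
* Gini is the only split criterion; class weights and pruning are not
  implemented (the depth cap is the capacity control).
* The exported C code is emitted and verified structurally, but not
  compiled by this package.
* PCA ranking is unsupervised; a label-aware ranking would likely
  saturate the mixed curve earlier.
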
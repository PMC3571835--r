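---
title: "Methods: hyperspectral variety discrimination in hyperseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral variety discrimination in hyperseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperseed)
```

## The measurement model

A line-scan VIS-NIR imager produces a *hypercube*: a rows × cols × bands
array in which every pixel holds a reflectance spectrum. `hyperseed` treats
square pixel windows (ROIs) of such cubes as samples and asks whether six
seed varieties can be told apart from (a) the sample's mean reflectance
spectrum and (b) the spatial texture of a few informative band images.

Raw camera counts are converted to relative reflectance with two reference
acquisitions — a white standard `W` (maximum reflectance under identical
optics and illumination) and a dark frame `B` (lens capped):

$$I = \frac{I_0 - B}{W - B}$$

applied per pixel and band. Where `W − B ≤ eps` (default `1e-8` on the
raw-intensity scale) the output is set to 0 and the voxel is recorded in a
degenerate-denominator mask rather than propagating an infinity. Calibrated
values are deliberately **not clipped**: reflectances outside [0, 1.5] are
only counted in the QC summary, because clipping would distort the
gray-level statistics that the texture stage depends on. The calibration is
invariant to any common positive rescaling of `I0`, `W`, `B`, which is what
makes it a flat-field correction.

Band edges of VIS-NIR sensors are noisy, so analysis restricts to a closed
interior wavelength window, by default 500–900 nm. Cropping keeps every
band whose wavelength lies in `[lo, hi]`; both endpoints are included so a
band exactly at the boundary is never silently dropped.

ROIs are drawn by seeded rejection sampling and must not overlap: texture
statistics of overlapping windows would be duplicated across "samples" and
would understate the variance of every downstream estimate. The sampler
stops after `10 n` proposals and reports the achievable count if `n`
non-overlapping windows do not fit.

## Spectral features

Each ROI is collapsed to its mean spectrum (arithmetic mean of all pixel
spectra per band). The sample × band matrix is then compressed two ways:

* **PCA** — mean-centred singular value decomposition. SVD is used instead
  of eigendecomposing the covariance matrix for numerical stability; the
  test suite verifies their equivalence (up to column sign) on random
  matrices. Each loading's sign is fixed so that its largest-magnitude
  element is positive, removing the arbitrary sign flip from serialized
  models and tests.
* **KPCA** — PCA in the feature space of the Gaussian kernel
  `K(u,v) = exp(−‖u−v‖²/(2σ²ₖ))`. The training kernel is double-centred,
  eigendecomposed, and eigenvectors are rescaled by `1/√λ` so the implicit
  feature-space components have unit norm; out-of-sample points are centred
  with the stored training row means and grand mean. With `σ²ₖ = "auto"`
  the median of pairwise squared distances is used (the median heuristic) —
  the classical studies never report their width, and the median heuristic
  is the standard self-tuning choice. A linear-kernel hook exists purely so
  tests can confirm that KPCA degenerates exactly to PCA.

Both keep `k = 3` components by default: in practice the first three
components of smooth reflectance spectra carry ~99% of the variance (the
acceptance script recomputes this on the synthetic study), and three
scores per sample is the regime the downstream classifiers were designed
around.

## Effective wavelengths

For on-line use one wants a handful of monochromatic images instead of 500
bands. `hyperseed` follows the loading-extrema approach: PCA is fitted with
*pixels* as observations (a montage of calibration-set ROI pixels;
`montage_pixels = 1000` per ROI are subsampled with a fixed seed to bound
memory), and the per-band loading profiles of the first three components
are scanned for local extrema in a centred window (`window = 5` bands,
odd). Plateau ties resolve to the lowest index; profile endpoints are
detected with a truncated window but **excluded from selection** by
default, since spectrum edges are exactly where the signal-to-noise
argument for cropping applies.

How to go from many extrema to three named wavelengths is genuinely open;
the package ranks pooled interior extrema by absolute loading value and
greedily keeps the strongest `k_bands = 3` subject to a pairwise
separation of `merge_window_nm = 10` nm (near-coincident extrema from
different components collapse onto the stronger one). The ranking is
deterministic with index-then-component tie-breaks, so the selection is
invariant to candidate order. The band set is fitted on calibration
samples only and then applied unchanged to prediction samples — the
selection is data-driven, so anything else would leak test information.

## Texture features

Each selected band image is min–max quantized to `Ng = 8` gray levels
(`level = ⌊Ng (v − min)/(max − min)⌋`, maximum mapped to `Ng − 1`). Eight
levels is the era-typical default of texture toolboxes; the value is
configurable and all tests fix it explicitly. A relative spread below
1e-10 is treated as a constant image (level 0 everywhere): min–max binning
would otherwise amplify pure floating-point noise to full-range texture.

The gray-level co-occurrence matrix counts ordered level pairs at offset
(0, 1) — direction 0°, distance 1 pixel — and is symmetrized (Haralick's
original definition) before normalizing to sum 1. Four scalars summarize
it:

| feature | formula | degenerate convention |
|---|---|---|
| contrast | `Σ (i−j)² p(i,j)` | 0 for a constant image |
| homogeneity | `Σ p(i,j)/(1+|i−j|)` | 1 |
| energy | `Σ p(i,j)²` | 1 |
| correlation | `Σ (i−μᵢ)(j−μⱼ) p(i,j)/(σᵢσⱼ)` | 0 when `σᵢσⱼ = 0` |

Homogeneity uses the inverse-difference form `1/(1+|i−j|)` exposed by
mainstream tools; Haralick variants differ, so this is stated explicitly.
The correlation convention keeps feature vectors numeric rather than
introducing missing values. Three selected bands × four features give the
classical 12 texture variables per sample, concatenated band-major in
(contrast, homogeneity, energy, correlation) order.

## Classifiers

**LS-SVM.** The least-squares SVM replaces the SVM quadratic program with
one linear system: with `Ω_ij = y_i y_j K(x_i, x_j)`,

$$\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
\begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ \mathbf{1} \end{bmatrix}$$

and `f(x) = Σ α_i y_i K(x_i, x) + b`. The kernel is parameterized
`K(u,v) = exp(−‖u−v‖²/σ²)` — **σ² divides the squared distance directly**,
so the grid-searched σ² matches the symbol used throughout the LS-SVM
literature; note this differs from the `2σ²` form used by KPCA above.
Multiclass problems use one-vs-one voting (`C(C−1)/2` machines, each
linear system stays small — the standard scheme of period LS-SVM
toolboxes), with vote ties resolved to the earliest class in lexicographic
order.

Hyperparameters are grid-searched over `γ ∈ 2⁻¹…2¹⁰`, `σ² ∈ 2¹…2¹⁵`
(integer exponent steps) by seeded stratified 10-fold cross-validation.
The selection criterion is RMSECV computed on integer class codes
(position in the sorted class list) of predicted vs true labels — RMSE on
class codes is how regression-style chemometrics software scores
classification CV, and the same sorted-class coding is shared by the grid
search and the final model so the two cannot disagree. RMSECV ties break
toward smaller σ², then smaller γ (the smoother, more regularized model).

**BPNN.** A single hidden layer of 9 logistic units (a "9" specified for a
period network is read as 9 hidden *nodes*; a nine-hidden-layer sigmoid
network would not have been trainable with 2000s-era methods), logistic
output units against one-hot targets, full-batch gradient descent with
classical momentum 0.6 ("dynamic parameter"), MSE goal 1e-5, at most 1,000
epochs, weights initialized uniform(−0.5, 0.5) from a seeded RNG. The
gradient is the per-sample-averaged delta rule; with that scaling a step
size of 0.5 (default, configurable) trains cleanly where 0.1 barely moves
the weights within the epoch budget. Inputs are min–max scaled to [0, 1]
with training-set ranges (stored in the model), the standard conditioning
step for sigmoid networks. Prediction applies the ±0.5 recognition band: a
sample is assigned class c only if output unit c is within 0.5 of 1 *and*
every other unit is within 0.5 of 0; anything else is "unrecognized" and
counts as an error, which is why BPNN accuracies can sit far below LS-SVM
accuracies on the same features.

## The orchestrated experiment

`run_experiment()` wires the stages together for the four input
combinations (PC, PC+GLCM, KPC, KPC+GLCM) × two classifiers and returns a
summary table with calibration and prediction accuracy (reported to 2
decimals; full precision retained in the per-model reports, whose
confusion-matrix trace always reconciles with the accuracy). Design
choices:

* The stratified split draws `n_cal_per_class` calibration samples per
  class (default: the classical 40-of-55 proportion applied to the
  dataset at hand) and is seeded.
* *No leakage*: the split, PCA/KPCA fits, band selection, feature scaling
  statistics and the grid search see calibration samples only; the result
  object records the sample ids each data-driven stage saw so this is
  assertable.
* Features are z-scored with calibration-set statistics before
  classification (`autoscale = TRUE`). GLCM contrast lives on a
  `(Ng−1)²` scale while PC scores live near zero; without autoscaling the
  texture block would dominate every RBF distance.
* All stage seeds derive deterministically from the master seed, and all
  randomness goes through a scoped RNG that restores the caller's state,
  so a rerun with the same dataset and seed is bit-identical.
* Class order is lexicographic throughout (labels "I"…"VI" sort
  correctly).

## The synthetic study

Real seed cubes are instrument-bound and rarely deposited, so the package
generates its own six-variety study with known structure:

* Each variety has a smooth signature over 380–1,030 nm — a baseline plus
  Gaussian bumps, values kept inside (0, 1). Variety I is dark (baseline
  0.08), emulating a black-testa seed among yellow ones.
* Each variety has a deterministic spatial texture (stripes, checker or
  blob lattice) with its own period and amplitude, multiplied onto the
  signature: `refl = gain · s(λ) · (1 + t(r, c)) + ε`.
* `gain` is a per-sample illumination factor (sd 0.02 by default),
  emulating shot-to-shot lamp drift; `ε` is i.i.d. Gaussian noise
  (sd 0.01), a deliberately simple sensor-noise model.
* Two *twin pairs*, (II, V) and (IV, VI), have signatures that are exact
  scalar multiples 0.4% apart. Because illumination gain also acts as a
  scalar on the signature, the twins' mean-spectrum distributions overlap
  almost completely — only their textures differ. This is the engineered
  analogue of same-coloured varieties with different seed-coat structure,
  and it is what makes the PC-vs-PC+GLCM comparison informative: on this
  generator, spectral-only models *must* confuse the twins while
  texture-augmented models can resolve them. The packaged defaults keep
  all non-twin signature distances above 0.3 (L2 on a 128-band grid) and
  twin distances below 0.05.
* The raw cubes are produced by inverting the calibration equation through
  the session's reference frames (white 0.95 with a 2% spatial ripple,
  black 0.02), so `calibrate_reflectance()` recovers the reflectance field
  exactly in the noiseless case — an identity the tests exploit.
* A manifest (all parameters + seed) regenerates any dataset
  bit-identically.

What the generator does **not** model: seed-shape segmentation (samples
are square ROIs, as in tray-imaging practice), wavelength-correlated
noise, specular highlights, detector smile/keystone, or any radiometric
realism of actual maize. Passing the end-to-end checks on this generator
therefore demonstrates that the pipeline machinery is correct and
leak-free and that texture features add exactly the kind of information
they are designed to add — it does not certify accuracy figures on real
seeds.

## Problem sizes and numerical conventions

Default desk-scale geometry is 64×64-pixel ROIs with 128 bands (the
full-size 100×100 × 512-band geometry is available through the generator
arguments; nothing in the code depends on the reduced size). The
end-to-end study used by the acceptance script runs 6 × 20 samples; tests
use smaller cubes still. Other conventions collected in one place:
1-based, row-major spatial coordinates with the origin at top-left;
closed wavelength intervals; ENVI data types restricted to float32 and
uint16 (others rejected loudly); loadings sign-fixed as above; eigenvalue
positivity threshold `1e-12` relative for KPCA; LS-SVM singularity
surfaces as an error suggesting a larger γ rather than a silent
pseudo-inverse.

## Known limitations

* The BPNN is a faithful period piece — batch gradient descent with
  momentum — and is expected to underperform the LS-SVM, particularly
  under the strict ±0.5 recognition band; it is included for comparison,
  not as the recommended classifier.
* Grid-search RMSECV on class codes penalizes confusions between
  distant-coded classes more than adjacent ones; with six roughly
  symmetric classes this has little effect on the argmin, but it is a
  coding artefact to be aware of.
* `read_envi()` supports the interleaves and data types this pipeline
  emits; it is not a general ENVI implementation (no BIL tiling, no
  complex types, no external header offsets).
* KPCA out-of-sample projection assumes the training set is retained in
  the model; for very large studies a Nyström approximation would be
  needed, which is out of scope here.
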
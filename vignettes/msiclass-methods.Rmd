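---
title: "Discriminating tissue classes from MALDI-MSI data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating tissue classes from MALDI-MSI data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiclass)
```

# The problem

MALDI mass spectrometry imaging (MSI) acquires a full mass spectrum at every
pixel of a tissue section, so a single acquisition is a cube: two spatial
axes and one m/z axis. Given paired acquisitions of pathological and healthy
tissue from a cohort of patients, the analytic goal is to decide, per tissue
and per pixel, whether its metabo-lipidomic profile looks pathological, and
to name the ions that drive the distinction. `msiclass` implements that
workflow end to end: imzML I/O, spectral preprocessing, object-level PCA
with per-pixel score maps, PLS-DA classification with VIP variable
selection and leave-one-patient-out cross-validation, per-pixel
classification maps, bisecting k-means spatial segmentation with Pearson
colocalization of ions, and formula/adduct annotation of reported m/z
values. A synthetic phantom generator provides data with known ground truth
for every stage.

# Preprocessing chain

The supervised chain is, in order:

1. **Peak binning** (`bin_peaks()`): fixed half-open bins
   `[m0 + k·bw, m0 + (k+1)·bw)` with the bin origin at the lower
   acquisition bound and `bw = 0.2` Da by default. Per pixel and bin the
   intensity is the *maximum* raw intensity in the bin; the bin center
   becomes the variable m/z. The half-open convention makes binning
   bit-reproducible; a point exactly on an edge goes to the upper bin.
2. **TIC normalization** (`normalize_tic()`): each spectrum is rescaled so
   its total ion count equals the mean pre-normalization row sum. Rescaling
   to the dataset mean (rather than to 1) keeps intensities on their
   original scale, which matters later because the noise gate and the log
   offset are scale-dependent. Zero-sum spectra are left alone and flagged.
3. **AsLS baseline removal** (`asls_correct()`), per pixel spectrum: the
   baseline `z` minimizes `Σ wᵢ(yᵢ − zᵢ)² + λ Σ (Δ²z)²` with weights
   updated per iteration to `p` above the baseline and `1 − p` below
   (`p = 0.005`, `λ = 1e8`, 20 iterations by default). `λ` of that
   magnitude is the standard setting for spectra of a few thousand
   channels; values like 10² barely smooth at all.
4. **MAD noise gate** (`mad_noise_gate()`): per spectrum, the noise scale
   is the raw (unscaled) median absolute deviation of the row around its
   row median; entries at or below `2.5 × MAD` are zeroed, entries strictly
   above are kept. The per-spectrum scope treats signal-to-noise as a
   property of each acquisition position; a global variant is available in
   the configuration.
5. **Pixel-fraction filter** (`pixel_fraction_filter()`): a variable with a
   nonzero signal in strictly fewer than 35 % of the pixels is replaced by
   its column minimum, suppressing sparse variables while preserving matrix
   shape. Computed across the merged dataset by default (per image via
   configuration).
6. **Log transform** (`log_transform()`): `ln(value + offset)` with the
   offset defaulting to the smallest positive matrix entry — the data do
   not say how zeros should be handled before the log, and this choice maps
   zeros to the finite floor closest to the data scale.

Auto-scaling (`fit_autoscale()` / `apply_autoscale()`) is *not* part of the
chain: it is fitted on training objects only (mean and n−1 standard
deviation per variable; zero-variance variables get divisor 1) and the same
parameters are applied to test objects and to pixel rows when projecting
maps. Morphological top-hat baseline removal (`tophat_baseline()`) and RMS
normalization (`normalize_rms()`) are provided for the vendor-side
segmentation workflow but are not in the default supervised chain.

## Numerical notes on AsLS

The normal equations `(W + λDᵀD) z = W y` are pentadiagonal and solved by a
banded Cholesky factorization in C++ (O(n) per solve), followed by a few
iterative-refinement passes: at `λ = 1e8` the system's conditioning costs a
plain solve several digits, and refinement restores near-machine accuracy.
One property worth knowing: the *solve* agrees with a dense reference to
better than 1e−8 relative, but the full 20-iteration loop is chaotic at
that level for any two independent solvers, because the weight update
thresholds `y > z` and the asymmetric fit structurally parks a fraction
`≈ p` of the points within numerical distance of the baseline. The test
suite therefore checks full-loop equivalence at a conditioning where weight
decisions are unambiguous (`λ = 1e4`) and the default-strength system
(`λ = 1e8`, 2000 channels) at fixed first-iteration weights.

# Object-level modeling

Supervised and unsupervised models are trained on **objects**: one median
spectrum per image (`median_objects()`), the per-variable sample median
over the image's tissue pixels (background-labeled pixels are excluded from
medians but kept in the matrix so maps cover the full grid). Medians give
one observation per tissue, which matches the clinical unit of replication
and is robust to intra-tissue heterogeneity.

**PCA** (`msi_pca()`) is computed by SVD of the auto-scaled training object
table, with a deterministic sign convention (each loading column's
largest-magnitude element is positive). Training loadings and scaling are
then applied to every pixel of any image (`score_map()`) to visualize the
components spatially.

**PLS-DA** (`plsda()`) uses NIPALS PLS1 on the auto-scaled spectra and the
centered binary response (healthy = 1, pathological = 0): per component,
weight `wₐ ∝ Xᵀy` (unit norm), scores `tₐ = Xwₐ`, loadings
`pₐ = Xᵀtₐ/tₐᵀtₐ`, `qₐ = yᵀtₐ/tₐᵀtₐ`, then deflation of `X` and `y`. For a
single response NIPALS is numerically equivalent to SIMPLS, and at full
rank its predictions coincide with ordinary least squares (a test asserts
both). Class assignment applies one-dimensional Gaussian LDA with pooled
variance and equal priors to the predicted response, which reduces to the
midpoint of the class means; equal priors reflect the balanced object-level
design (one image per class per patient), not the unbalanced pixel counts.

**VIP** (`vip_scores()`):
`VIPⱼ = sqrt( p Σₐ SSYₐ (wⱼₐ/‖wₐ‖)² / Σₐ SSYₐ )` with
`SSYₐ = qₐ² tₐᵀtₐ`, so `Σⱼ VIPⱼ² = p` (asserted to 1e−6 on every fitted
model). Variable selection keeps `VIP > 2`, strictly.

**Cross-validation** (`lopo_cv()`) leaves one *patient* out per fold — both
of that patient's images — and refits everything inside the fold,
auto-scaling included. With VIP selection requested, the selection itself
is recomputed inside each training fold (from a fold model at `max_lv`
components) before refitting on the reduced variables, so no information
about the held-out patient can leak through the variable list. The optimal
component count maximizes CV accuracy; ties resolve toward fewer components
(parsimony). Sensitivity and specificity take the healthy class as
positive. Metrics are reported at the object level; per-pixel percent
correct (`classify_pixels()`) is reported separately per image, since
pathological sections legitimately contain healthy regions and a pixel
denominator mixes the two questions.

# Segmentation and colocalization

`bisecting_kmeans()` recursively 2-means-splits the leaf with the largest
within-cluster sum of squares (ties: larger pixel count, then lower node
id), using Euclidean distance on the preprocessed spectra. The 2-means step
is deterministic: the first center is the point farthest from the leaf
centroid, the second the point farthest from the first, then Lloyd
iterations to a 1e−8 tolerance (at most 300). Determinism means a given
matrix always yields the same tree — there is no seed sensitivity to
document away. For each leaf cluster, `colocalize()` computes the Pearson
correlation between the cluster's spatial indicator mask and every
variable's intensity image and reports variables with `r ≥ 0.5` (inclusive,
matching the selection actually applied to reported ion lists). No spatial
denoising is applied before clustering; commercial pipelines apply a
proprietary edge-preserving filter at this point, and a hook in the
configuration is the honest substitute for guessing its algorithm.

# Annotation

`monoisotopic_mass()` sums most-abundant-isotope masses (C, H, N, O, P, S,
Na, K, Cl supported); `adduct_mz()` adds electron-corrected deltas for
[M+H]⁺, [M+Na]⁺, [M+K]⁺, [M−H]⁻, [M+Cl]⁻. Electron correction matters at
the fifth decimal: the standard positive-mode phosphatidylcholine calibrant
PC(16:0/18:1) gives 760.58508 ([M+H]⁺), 782.56702 ([M+Na]⁺, truncated at
the fifth decimal as instrument lock-mass tables print it; the computed
value is 782.5670259) and 798.54096 ([M+K]⁺). `match_peaks()` reports every
(peak, compound, adduct) combination within the tolerance, sorted by
absolute ppm error, flagging peaks with multiple hits as ambiguous. FT-ICR
style matching uses ppm (0.2 narrow / 5 wide); for TOF data binned at 0.2
Da a Da window (`tol_da`) is the meaningful unit. Lipid shorthand
("PC 32:0") is deliberately not parsed into formulas: published shorthand /
formula pairs are not always consistent, so the compound table must carry
explicit formulas, and the table shipped in `inst/extdata` flags the two
rows whose printed m/z cannot be reproduced from their own formula and
adduct (`note = "mass_inconsistent"`) rather than silently correcting them.

# The phantom generator

`generate_phantom()` draws, per pixel, intensity
`baseline(mz) + tic · patientⱼ · region_mean + noise`, truncated at zero:

* channels are equally spaced across the acquisition range so each lands in
  its own 0.2-Da bin; only a fraction (`signal_fraction`, default 0.4) are
  true ions with base intensities `≈ 100` and ~30 % log-normal spread — the
  remaining channels carry only baseline and noise, emulating the noise
  floor that the MAD gate and pixel-fraction filter exist to remove;
* `n_discriminant` ion channels differ between tumor and non-tumor region
  means by a multiplicative fold change, alternating up/down;
* the pathological image contains a contiguous tumor region (disc covering
  ≈ 64 % of the grid by default, so the image median reflects tumor tissue)
  plus adjacent non-tumor tissue; the healthy image is homogeneous;
* per-pixel TIC factors are log-normal with mean 1 (CV
  `tic_variation_cv`); the patient random effect is a log-normal *per
  channel* multiplier vector shared by both of a patient's images. The
  per-channel form matters: a single global patient factor would be removed
  exactly by TIC normalization, leaving object-level spectra almost
  noise-free and making every channel spuriously class-correlated through
  normalization closure. Per-channel effects are also the realistic
  reading of between-subject metabolome variability;
* additive Gaussian noise with one global sd, `noise_sd ×` (mean ion
  intensity), present on empty channels too.

Three named scenarios fix the study conditions. `separable` is the
simulation analog of a cleanly separated two-class cohort: 7 patients × 2
images, 40×40 pixels, 500 channels, 25 discriminant channels at fold 3,
noise sd 5 % — strong planted effects that the full pipeline must convert
into 100 % leave-one-patient-out accuracy for both the full and the
VIP-reduced model. `noisy` (fold 1.3, noise sd 60 %, patient sd 0.4 on a
20×20 grid) produces genuine class overlap for robustness work. `null`
plants nothing at all and runs on a 16×16 grid with 300 channels — sizes
chosen once so that 20-seed replication suites remain cheap; with no
planted effect the grid size does not change the null distribution's
location, only its spread.

What passing on phantoms does **not** show: the generator has delta-like
peaks (no peak shape or width structure), no isotope envelopes, no chemical
/ matrix background structure, no spatial autocorrelation of noise, and no
histology-driven heterogeneity inside regions. Results on real tissue
depend on exactly those features; the phantoms validate the statistical
machinery, not instrument physics.

## The null-scenario chance check

The null check compares leave-one-patient-out accuracy, pooled over 20
seeds, against a binomial band **at fixed component counts**. The accuracy
at the *selected* optimum is deliberately not used as the chance statistic:
with 14 objects, taking the maximum over five component counts inflates the
expectation above 50 % by selection alone (order statistics of five
correlated binomials), so "optimum accuracy ≈ 55 % under the null" is
expected behavior, not leakage.

# Design choices that were genuinely open

* **Background pixels**: masks may label off-tissue pixels; these are
  excluded from object medians and from pixel-accuracy denominators but
  retained in the matrix so score and classification maps cover the full
  grid.
* **Chain order**: binning precedes normalization so TIC is computed on the
  variables actually analyzed; AsLS runs per pixel on binned values; the
  gate precedes the pixel-fraction filter, whose "signal" definition is a
  post-gate nonzero entry.
* **VIP selection inside CV**: per-fold reselection is the leakage-free
  reading; reusing a full-data selection is available by refitting
  manually, but the reported CV numbers always come from per-fold
  selection. VIP scores inside a fold come from the fold's full-variable
  model at the maximum component count under evaluation.
* **Modulation direction** in the ion report is the sign of the
  tumor-minus-healthy difference of object-level medians — direction only,
  as magnitudes after TIC normalization and log transform are not fold
  changes.
* **Positive/negative mode** are independent runs; nothing is shared
  across polarities.

# Problem sizes and determinism

The test suite and the acceptance script run the separable scenario at its
stated size (22,400 spectra × 500 channels through the full chain,
~25 s for preprocessing on one core), 20 null-scenario replicates at
16×16×300, and oracle comparisons on spectra up to 2000 channels. Every
stochastic step — phantom generation and nothing else; PCA, PLS, and the
bisecting split are deterministic — flows from one explicit seed, and a
rerun with the same configuration reproduces bit-identical matrices and
reports.

# Known limitations

* imzML support covers continuous and processed mode with uncompressed
  32/64-bit float arrays — the subset the writer emits and common
  converters produce; compressed or integer-encoded files are rejected.
* No spectral alignment or recalibration, no isotope-pattern scoring, no
  MS/MS evidence: annotation is mass arithmetic, and at TOF accuracy it is
  putative by construction.
* The LDA threshold is univariate with equal priors; cost-sensitive or
  prior-weighted classification would need the pixel class balance, which
  the object-level design intentionally ignores.
* Segmentation is per image; no joint multi-image segmentation.
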
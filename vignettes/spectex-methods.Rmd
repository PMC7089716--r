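---
title: "Spectral CT texture: simulation, reconstruction and classification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral CT texture: simulation, reconstruction and classification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectex)
```

# Scope

`spectex` is a desk-scale laboratory for two connected problems in
photon-counting (multi-energy) CT:

1. **Reconstruction.** Each energy channel of a photon-counting scan is
   photon-starved, so channel-by-channel reconstruction is noisy. The
   package implements a Bayesian reconstruction that couples channels
   through a low-rank prior and preserves within-tissue texture through a
   tissue-specific Markov-random-field (MRF) prior learned from a
   full-dose image (the LRTP algorithm).
2. **Classification.** Multi-energy data enrich tissue texture. The
   package implements the gray-level co-occurrence (GLCM) / Haralick
   descriptor pipeline and a Gini-ranked random-forest harness to measure
   whether that enrichment improves benign-vs-malignant discrimination of
   soft-tissue lesions.

Both study datasets that motivated this design are private, so the
package ships a synthetic world — a 4-tissue chest phantom and a
polyp-like lesion cohort — that reproduces the *structure* of those
experiments, not their numbers.

# The reconstruction model

The multi-channel image $\mathcal{X}$ (channels $\times$ pixels) is
estimated by minimizing

$$\|\mathcal{A}\mathcal{X}-\mathcal{Y}\|_2^2
  + \lambda\|\mathcal{X}\|_* + \beta R(\mathcal{X}),$$

where $\mathcal{A}$ is the per-channel parallel-beam projector,
$\mathcal{Y}$ the measured (log-transformed) line integrals,
$\|\cdot\|_*$ the nuclear norm of the channels-by-pixels unfolding, and
$R$ the texture prior

$$R(\mathcal{X}) = \sum_k \sum_{r=1}^{R} \sum_{j \in \mathrm{Region}(r)}
  \sum_{m \in \Omega_j} w^{FD}_{jmk}\,(x_{jk}-x_{mk})^2 .$$

The weights $w^{FD}$ are one shared $7\times7$ kernel per (tissue,
channel), fitted on the full-dose image by least-squares autoregression
over region-interior pixels and then normalized to sum 1, so $R$ is a
consensus penalty: it is zero exactly when every pixel equals its
kernel-weighted neighborhood mean within its tissue. The estimator
behind the weights is a design choice of this package — the source
description leaves the fitting equation blank — and least squares is the
natural reading of "predicting" a pixel from its neighborhood.

**Boundary handling.** Pixels whose window crosses the region (or image)
boundary contribute the terms for the neighbors they do have, at their
raw kernel weights. An earlier design renormalized each pixel's used
weights to sum 1; that variant is *not* what the quadruple sum above
says, disagrees with hand enumeration on tiny examples (a $3\times3$
image with a unit center pixel and the uniform $1/8$ kernel must give
$R = 2$), and divides by near-zero sums when fitted kernels carry
negative weights. The raw-weight sum is used throughout.

**Splitting.** The objective is minimized by an augmented-Lagrangian
loop with auxiliary low-rank variable $\mathcal{D}$ and scaled dual
$\mathcal{V}$: a data/prior update of $\mathcal{X}$, then
$\mathcal{D} \leftarrow \mathrm{SVT}_{\lambda/2\mu}(\mathcal{X}+\mathcal{V})$,
then $\mathcal{V} \leftarrow \mathcal{V}+\mathcal{X}-\mathcal{D}$. The
singular-value threshold $\lambda/(2\mu)$ follows from the quadratic
penalty exactly as written (no extra $\tfrac12$ convention). The
$\mathcal{X}$ update is inexact: a few SART-preconditioned gradient
sweeps with backtracking, which reduce to plain SART passes when
$\beta = \mu = 0$. The loop stops when the relative change of
$\mathcal{X}$ falls below `tol` (default $10^{-4}$) or after `n_outer`
iterations.

**Default weights.** The source description reports no values for
$(\lambda, \beta, \mu)$ and prescribes choosing them by grid search on
the shipped fixture; `lrtp_default_config()` records the result:
$\beta = 3000$, $\lambda = 3000$, $\mu = 30$ (threshold 50 HU) on the
64-pixel, five-channel, $10^4$-photons-per-channel chest fixture. On
that fixture the texture prior does most of the work and the low-rank
term mainly suppresses channel-decorrelated noise; both directions of
the Table-style ordering (lower RMSE, higher SSIM than SART on every
channel) are computed by the test suite, not asserted from literature.

**Units.** Measurements are mapped into the HU domain before iterating
(using $\mu = \mu_w(1 + \mathrm{HU}/1000)$ and a smooth water-attenuation
curve $\mu_w(E)$), so the prior, the nuclear norm and the output all
operate on CT values and the learned kernels apply without rescaling.

# The synthetic world

**Chest phantom** (`make_chest_phantom`): a 2D slice with two elliptical
lungs, nine rib cross-sections, a subcutaneous fat layer and muscle
elsewhere — exactly four tissues, mildly jittered per seed. Rib inserts
are sized so each still has interior pixels after eroding by the
$7\times7$ window radius at side 64, which weight learning requires.

**Spectral response** (`default_response_table`): published response
curves for the soft-tissue materials exist only as a figure, so the
table uses linear-in-energy curves anchored at typical 75 keV values
(fat $-90$, cellular tissue $+50$, water $0$, lung $-800$, bone $+1000$,
muscle $+40$ HU) with low-energy amplification factors; the fat factor
makes $\mathrm{HU}_{fat}(35)/\mathrm{HU}_{fat}(75) = 1.3$. Water is zero
everywhere, fat negative, cellular tissue positive, and every material's
$|\mathrm{HU}|$ grows toward low keV — the qualitative constraints the
simulation needs. The table lives in CSV-compatible form so measured
curves can be substituted.

**Acquisition** (`project_spectral`): parallel-beam geometry (the
simplest operator with an exact adjoint; the sparse system matrix makes
back-projection the literal transpose), Poisson counting noise, and a
photon budget split evenly over channels so each channel is
photon-starved — the defining regime of photon-counting CT. Defaults (90
angles at side 64, $10^4$ photons/channel/bin) are package choices; no
acquisition parameters were reported.

**Lesion cohort** (`make_lesion_cohort`): 63 lesions (31 benign / 32
malignant) by default, matching the printed cohort of the motivating
study, with class-mean diameters 39.9 mm (count-weighted adenoma mean)
and 43.9 mm (adenocarcinoma). Each lesion is a sphere of pure-material
voxels (fat / cellular tissue / water) obtained by thresholding a
spatially correlated Gaussian random field at class-specific mixing
fractions. No generative texture model for real polyps is published, so
the class contrast is a design choice made once: benign lesions use a 6
mm correlation length and fractions (0.20, 0.60, 0.20); malignant use 3
mm and (0.25, 0.50, 0.25). Per-lesion log-normal jitter (sd 0.25 on
fractions, 0.10 on correlation length) makes classes overlap in
first-order statistics, as patient cohorts do; the texture scale
difference is what the descriptors must find. Consequences a reader
should keep in mind: a green classification test establishes that the
pipeline detects *this kind* of heterogeneity difference, not that real
polyps are separable at any particular AUC; and because voxels are pure
materials, partial-volume effects are absent by construction.

# Texture features

GLCMs are accumulated with both pair orders (hence symmetric) and
normalized; directions are the symmetry-reduced unit offsets — 4 of 8 in
2D, 13 of 26 in 3D — in lexicographic order with the first nonzero
component positive. Gray levels default to $G = 32$ uniform bins over
the ROI min-max range (quantization level and windowing were not
reported; ROI min-max makes descriptors invariant to constant HU
shifts). The 14 Haralick measures use natural logs, $0\log 0 = 0$, sum
variance centered on the sum average, and return defined values in
degenerate cases (correlation and information measures 0 for degenerate
marginals; maximal correlation coefficient 0 for a rank-deficient Q).
The 28-entry descriptor is the per-measure mean block followed by the
per-measure range block over the 13 directions, in a frozen order.
Difference images subtract neighboring channels (5 channels give 4
differences). Per-channel descriptors are concatenated for multi-channel
inputs — whether the original study concatenated or pooled is not
described, and concatenation is this package's default.

# Classification harness

The random-forest engine (Gini-impurity CART trees, bagging,
mean-decrease-in-impurity importance, out-of-bag scores) is implemented
in compiled code inside the package because no forest package is
available in the target environment; it follows the stated protocol:
3000 trees by default and $\mathrm{round}(\sqrt{p})$ candidate features
per node (5 for 28 features). Features are first ranked by Gini
importance, then forward stepwise selection evaluates nested prefixes by
out-of-bag AUC (exact ties to the smallest prefix). Evaluation uses
stratified two-fold cross-validation with fold swapping, repeated
(protocol: 100 runs; scaled-down counts in tests), reporting the
mean and standard deviation of per-run AUCs; the per-run AUC is the mean
of the two swapped folds (the aggregation across the swap was not
stated). Stratification is a package choice — plain random halves of a
31/32 cohort can produce degenerate folds at small n.

# Image quality metrics

RMSE and PSNR ($20\log_{10}(\mathrm{range}/\mathrm{RMSE})$, range from
the reference) are per channel. SSIM uses a $7\times7$ Gaussian window
($\sigma = 1.5$) with the standard constants. FSIM combines
phase-congruency similarity and Scharr gradient-magnitude similarity
weighted by the pointwise maximum phase congruency, with images rescaled
to 0–255 so the published constants ($T_1 = 0.85$, $T_2 = 160$) apply;
phase congruency uses a log-Gabor bank (4 scales, 4 orientations) with
median-based noise compensation. These are in-package implementations —
no R metric package is available in the target environment — and are
validated by identity, hand-arithmetic and monotonicity tests rather
than against a reference library.

# Numerical choices and degenerate inputs

* Count floor $c_{\min} = 1$ in the log transform keeps zero-photon bins
  finite.
* Poisson sampling switches to a seeded normal approximation above mean
  $10^7$, where exact generation overflows and the relative error is
  negligible.
* Constant tissue regions admit any normalized kernel; the uniform
  kernel is the tie-break. Constant images segment to an error, not to
  arbitrary masks.
* All randomness flows from explicit integer seeds through one local-RNG
  helper; derived per-stage seeds stay below $2^{31}$.
* Step-1 sweeps backtrack (halving) if a sweep would raise the Step-1
  cost, and the operation errors if cost still increases.

# Known limitations

* Parallel-beam only; no fan/cone-beam, scatter, beam hardening or
  detector crosstalk.
* The spectral model assumes pure-material voxels; the linear energy
  scaling is exact only under that assumption.
* The intensity-based segmentation stand-in requires tissues with
  well-separated mean HU; it is not a general segmentation method.
* The lesion generator's texture parameters are stand-ins, not estimates
  of real polyp statistics.
* Deep-learning comparison models and TV/LRTV/TDL reconstruction
  baselines are out of scope.
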
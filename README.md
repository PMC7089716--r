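# spectex

Desk-scale spectral (photon-counting) CT in R: simulate multi-energy
acquisitions of tissue-labeled phantoms, reconstruct them with a
low-rank + tissue-texture Bayesian prior, extract co-occurrence /
Haralick texture descriptors, and measure lesion-classification
performance with a random-forest cross-validation harness.

## Who this is for

Researchers studying how spectral CT's energy-enriched tissue texture
can be (1) *preserved* during low-photon-count image reconstruction and
(2) *exploited* for benign-vs-malignant lesion classification — and who
need a fully synthetic, seeded, end-to-end testbed because real
photon-counting and pathology-proven cohorts are hard to come by.

## The models

**Reconstruction (LRTP).** The multi-channel image
χ (channels × pixels) minimizes

```
‖𝒜χ − 𝒴‖² + λ‖χ‖_* + β R(χ)
R(χ) = Σ_k Σ_r Σ_{j∈Region(r)} Σ_{m∈Ω_j} w_jmk (x_jk − x_mk)²
```

where 𝒜 is a parallel-beam projector, ‖·‖_* the nuclear norm coupling
energy channels, and R a Markov-random-field texture prior whose 7×7
kernels w are learned per tissue and channel from a full-dose image by
least-squares autoregression. The objective is solved by an
augmented-Lagrangian splitting: an inexact SART-preconditioned update of
χ, singular-value thresholding at λ/(2μ) for the low-rank variable, and
a dual update.

**Classification (HF-RF).** Per lesion and energy channel, a gray-level
co-occurrence matrix is built for each of the 13 symmetry-reduced 3D
directions; each GLCM yields the 14 classical Haralick measures, and
their per-measure mean and range over directions form a 28-entry
descriptor. Descriptors feed a random forest (3000 trees, √p candidate
features per node) with Gini-importance ranking and forward stepwise
selection, evaluated by stratified two-fold cross-validation with fold
swapping, repeated with many random splits (AUC mean ± sd).

## Worked example

```r
library(spectex)

# --- reconstruction arm --------------------------------------------------
phantom <- make_chest_phantom(64, seed = 1)      # lung / bone / fat / muscle
truth   <- synthesize_spectral(phantom)          # 5 channels, 35..75 keV, HU
geom    <- proj_geometry(64, n_angles = 90)
sino    <- project_spectral(truth, geom, I0_total = 5e4, seed = 11)  # 1e4 photons/channel
masks   <- masks_from_phantom(phantom)
weights <- learn_mrf_weights(truth, masks)       # 7x7 texture kernels

sart <- sart_reconstruct(sino, geom, n_iters = 50)
lrtp <- lrtp_reconstruct(sino, geom, weights, masks, lrtp_default_config())
rbind(cbind(method = "sart", image_quality(truth, sart)),
      cbind(method = "lrtp", image_quality(truth, lrtp$chi)))
#>    method channel energy_keV    rmse   psnr   ssim   fsim
#> 1    sart       1         35 845.404  9.811 0.1881 0.3663
#> 2    sart       2         45 615.380 11.865 0.2460 0.4144
#> 3    sart       3         55 398.935 14.862 0.3199 0.4810
#> 4    sart       4         65 304.141 16.376 0.3566 0.5149
#> 5    sart       5         75 266.794 16.582 0.3634 0.5263
#> 6    lrtp       1         35  31.723 38.325 0.9743 0.9945
#> 7    lrtp       2         45  23.368 40.275 0.9831 0.9975
#> 8    lrtp       3         55  12.364 45.037 0.9877 0.9986
#> 9    lrtp       4         65   6.986 49.154 0.9948 0.9992
#> 10   lrtp       5         75   7.254 47.894 0.9944 0.9992
```

Read: at 10⁴ photons per channel per bin, plain SART (run to 50
view-sequential iterations, i.e. close to the noise-fitting least-squares
solution) leaves hundreds of HU of error per channel; the low-rank +
texture prior cuts the error by more than an order of magnitude and
restores structural similarity to the
noiseless ground truth on every channel.

```r
# --- classification arm --------------------------------------------------
cohort <- make_lesion_cohort(31, 32, seed = 7)   # benign vs malignant polyps
feats  <- cohort_features(cohort, levels = 16, seed = 1)  # 5 x 28 descriptors
cv <- twofold_cv(feats, classify_config(n_trees = 300), n_runs = 20, seed = 3)
cv
#> <cv_result> AUC 1.000 +/- 0.000 over 20 two-fold runs
```

Read: on the default synthetic cohort the texture-scale difference
between classes is fully detectable from the concatenated five-channel
descriptor (first-order voxel summaries of the same lesions score far
lower — see the acceptance tests). `glance(cv)` / `tidy(cv)` return the
summary and per-run AUCs as tibbles.

A full pipeline (simulate → project → recon → features → classify) runs
via `run_pipeline(default_pipeline_config())` or the thin CLI in
`exec/spectex`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch against the installed package — it generates its inputs, runs
the texture-descriptor pipeline, and writes the measured values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/phantom.R` — seeded chest phantom and lesion-cohort generators
* `R/spectral.R` — energy response tables, linear energy scaling, spectral synthesis
* `R/projector.R` — sparse-matrix parallel-beam projector, Poisson counting
* `R/texture_prior.R` — tissue segmentation stand-in, MRF weight learning, prior value/gradient
* `R/recon.R` — SART, singular-value thresholding, the LRTP splitting loop
* `R/glcm.R` — directions, quantization, GLCM, Haralick measures, 28-entry descriptor
* `R/classify.R` — random-forest harness, Gini ranking, forward selection, two-fold CV
* `R/quality.R` — RMSE / PSNR / SSIM / FSIM (phase congruency)
* `R/io.R`, `R/pipeline.R`, `exec/spectex` — text-format I/O, pipeline, CLI
* `src/forest.cpp` — the compiled CART random-forest engine
* `vignettes/spectex-methods.Rmd` — models, assumptions, parameter choices, limitations
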
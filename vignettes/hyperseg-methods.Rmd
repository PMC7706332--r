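---
title: "Methods: organ-level hyperspectral segmentation and its quantitative genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-level hyperspectral segmentation and its quantitative genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperseg)
```

## The problem and the model

A shortwave hyperspectral camera images a plant as an H×W×B cube: every
pixel carries B reflectance values across 546–1700 nm (243 bands on the
systems this package emulates, roughly 4.8 nm per band; band count is
configurable because vendor documentation is not always consistent about
it). The segmentation task is per-pixel four-class classification —
background (0), leaf (1), stalk (2), panicle (3) — using only each pixel's
spectrum, with no spatial context. This is deliberately the simplest
formulation: it needs only click-level training data, and whatever spatial
smoothing or convolutional modelling one might add later operates on top
of it.

The classification signal rests on three spectral contrasts:

* leaf and stalk are nearly indistinguishable in the visible range but
  separate widely on the near-infrared plateau (leaf reflectance well
  above stalk around 1100–1250 nm);
* the panicle differs from both in the visible range and tracks the stalk
  curve through the infrared;
* all living tissue shows water-absorption dips (a pronounced local
  minimum around 1400 nm) that dry background material lacks.

Downstream, segmentation maps are summarized into seven traits per plant
(three organ pixel counts, three pairwise ratios, height to apex), and
those traits feed a standard quantitative-genetics stack: genomic
relationship matrix, REML heritability (PVE), and a single-marker
mixed-model association scan.

## The synthetic-data generator

Every stage of the package is exercisable without external downloads
because the `synthetic_data` module generates study material with known
ground truth.

**Spectral signatures.** `make_signature_library()` builds per-class mean
curves as Gaussian bumps and dips on a logistic red-edge base. This
functional form was chosen because it reproduces, with a handful of
interpretable parameters, every qualitative contrast the classifiers
exploit: a shared low visible reflectance for leaf and stalk, a leaf NIR
plateau (~0.8) well above the stalk's (~0.5), a panicle that tracks the
stalk over 750–1700 nm, and a water dip centred at 1400 nm (with a
secondary feature near 1190 nm) for the three plant classes only. The
background curve is a gentle monotone ramp, so it provably has no local
reflectance minimum. Per-band noise is independent Gaussian and
homoscedastic within class (SD 0.015 for background, 0.045–0.050 for
plant classes, values chosen so that class mean separations span roughly
3–6 noise SDs in the informative regions — comfortably learnable, but not
trivially so at single-band level). Real sensor noise is neither Gaussian
nor band-independent; see Limitations.

**Plant geometry.** `plant_layout()` stylizes a plant as a vertical stalk
(default 5 px wide, matching the few-pixel stalk width typical at
greenhouse zoom levels), alternating straight leaves, and an elliptical
panicle atop the stalk. Painting order is leaves, then stalk, then
panicle, so every pixel has exactly one class. Row 1 is the top of the
image (raster convention). `panicle_height = 0` yields a vegetative plant
with only three classes present.

**Annotations.** `sample_annotations()` mimics a crowdsourced click
campaign: 10 pixels per class per image by default, uniform without
replacement within each image's class mask, each record carrying the full
pixel spectrum. Classes absent from an image are skipped (vegetative
plants contribute three classes), classes present but smaller than the
request raise an error naming the class.

**Genotypes and phenotypes.** `simulate_genotypes()` draws each SNP's
minor allele frequency uniformly from a range and genotypes with
heterozygote frequency 2p(1−p)(1−F); F = 0 is Hardy–Weinberg, F = 1 the
fully inbred panel appropriate when emulating a selfing-crop diversity
panel (the file-based pipeline uses F = 1 so that the standard
heterozygosity QC filter is meaningful). There is no linkage
disequilibrium by default. `simulate_phenotype()` builds
y = Σ βc gc + e and rescales the noise so the *realized* genetic variance
fraction equals the target h² exactly in-sample; this removes one layer of
Monte-Carlo noise from parameter-recovery tests without biasing REML
estimation. `simulate_population_images()` links causal SNPs to layout
parameters (e.g. panicle height) so that organ geometry — and therefore
every image-derived trait — has a known genetic architecture.

## Classifiers and evaluation protocol

Defaults: PLS-DA uses 10 components with an argmax decision on the class
response scores; the random forest 500 trees and √B candidate features per
split; the SVM an RBF kernel with cost 1 and γ = 1/B; the LASSO a
multinomial fit with penalty chosen by internal cross-validation; LDA has
no tunable parameters. QDA adds a ridge of 1e−6 · trace(S)/B to each class
covariance (escalated multiplicatively only if the Cholesky still fails),
so it survives classes with fewer records than bands — common in
small synthetic tests. The neural network is an in-package multilayer
perceptron — ReLU hidden layers, softmax output, minibatch SGD with
cross-entropy loss — because no installed R package provides
multi-hidden-layer ReLU networks; defaults are 4 hidden layers × 300
units, learning rate 5e−4, 200 epochs, batch 32 (epoch count, batch size
and stopping are exposed as configuration since reasonable values are
problem-dependent). `enumerate_ann_grid()` enumerates the full sweep of
3 depths × 5 widths × 40 uniformly drawn learning rates = 600
configurations; the test suite trains only small networks, since the
sweep's value is its enumeration contract, not 600 desk-scale fits.

Cross-validation is at the level of whole images: image ids are shuffled
with the seed and dealt round-robin into k folds (sizes differ by ≤1), so
all pixels from one image share a fold and accuracy is not inflated by
within-image correlation. The pooled out-of-fold predictions are scored as
total correct / total scored; per-class accuracies condition on the true
class. "Average" is pooled rather than macro-averaged — on balanced
annotation sets the two coincide, and pooled matches the accuracy
definition verbatim. `transfer_evaluate()` applies a trained model to a
foreign annotation set and adds an "average excluding" column for class
subsets (the maize tassel occupies the panicle slot but is a biologically
different organ, so it is conventionally excluded from one summary
column).

`gini_importance()` reports the random forest's mean decrease in Gini per
band, and `important_regions()` extracts maximal runs of bands above a
threshold (default 10) as closed wavelength intervals.

## Traits

Counts are exact class counts. Ratios are plain quotients; a zero
denominator (or a zero panicle count in panicle/stalk) produces `NA` plus
a missing-organ flag in batch mode, because incomplete plants occur in
real populations and are handled by exclusion lists, not exceptions.

Height to apex is the Euclidean distance from stalk base to panicle apex.
One orientation subtlety is fixed and documented: in raster coordinates
(row 1 on top) the stalk *base* is the maximum-row stalk pixel and the
panicle *apex* the minimum-row panicle pixel. Descriptions written under a
mathematical y-up convention call the base the "smallest y" stalk pixel; a
literal raster reading of such phrasing would instead measure
top-of-stalk to bottom-of-panicle, which is not a height. Ties on the
extreme row break to the smallest column index for determinism.

## Genetics

* **QC:** MAF ≥ 0.01 and heterozygote frequency ≤ 0.05, both over
  non-missing calls (the natural choice when missingness varies by SNP);
  the filter is idempotent and reports a per-SNP reason.
* **Kinship:** K = ZZ'/m with Z column-standardized, missing calls imputed
  to column means, zero-variance columns dropped with a warning.
* **PVE/heritability:** profile REML over the variance ratio
  λ = σ²g/σ²e on the eigenbasis of K: a 41-point log grid over
  [1e−6, 1e6] brackets the optimum, then `stats::optimize()`
  (golden-section, tolerance 1e−6) refines within the bracketing
  interval. PVE = λ̂/(1+λ̂), which equals σ²g/(σ²g+σ²e) and is the
  heritability estimate when mean(diag K) ≈ 1.
* **Association:** with K, the scan whitens y, covariates and genotypes
  under the null REML fit (rotate onto K's eigenbasis, rescale by
  1/√(λ̂ d_i + 1)) and then performs vectorized per-SNP least squares —
  i.e. an EMMAX-style single-marker mixed-model scan. This deliberately
  replaces iterative multi-locus bin-selection procedures: those
  algorithms' internals are a separate contribution, while the stand-in
  preserves the two stated controls (population structure via PC
  covariates, relatedness via the kinship component) in a transparent,
  testable form. SNPs with missing calls fall back to per-SNP
  complete-case regression; constant SNPs are skipped with `NA` and
  excluded from the Bonferroni denominator α/m. Gene lookup uses closed
  intervals [pos − w, pos + w] with w = 50 kb by default — the distance at
  which linkage disequilibrium typically decays below r² ≈ 0.2 in diverse
  sorghum panels; a gene exactly at the boundary is included.

## Numerical and design choices

* Flattening is row-major (pixel (i, j) → row (i−1)·W + j) and
  `reshape_predictions()` inverts it exactly; the pair is property-tested
  as an identity. The choice is arbitrary but must be fixed.
* Crop windows are half-open [start, stop) in 1-based indices; offsets are
  caller-supplied configuration since published image sizes typically
  state final dimensions only. Where an image size is quoted as
  "X × Y" (width × height), it maps to (rows = Y, cols = X).
* Band images normalise to [0, 1] by the image dtype's maximum (the
  PNG/TIFF readers do this on load); no white-reference calibration is
  attempted.
* The colour palette is a single module-level constant used by both
  `colorize()` and `decolorize()`; bit-exactness is part of the contract
  and tested by round trip.
* Seeds: every stochastic generator scopes its seed locally and restores
  the global RNG state, so library calls do not perturb user scripts.

## Problem sizes used by the test suite

The suite's statistical checks run at sizes chosen to give stable
Monte-Carlo behaviour on a single desk-scale core: classifier tests use
40-band, 120×84 images (8 plants, 10–50 clicks per class); REML recovery
uses one panel of n = 500 lines × 5000 SNPs with 50 phenotype replicates
per h² ∈ {0.2, 0.5, 0.8} (per-replicate SE of the PVE estimate at this
size is ≈ 0.15, so the mean over 50 replicates resolves ±0.1
comfortably); scan calibration uses n = 200–300 and 1000 SNPs; the
end-to-end planted-QTL test runs 20 replicates of an 80-line population
of 90×64, 40-band images with one large-effect SNP (+4 px panicle height
per allele) and requires the planted SNP to attain the smallest p-value
in ≥ 80% of replicates.

## What passing tests do and do not show

The generator is a model of the *contrasts* in real hyperspectral plant
images, not of their texture: noise is band-independent Gaussian, organs
are geometric primitives, there is no illumination gradient, midrib
structure, specular reflection, pot, or sensor calibration drift, and
synthetic genotypes carry no linkage disequilibrium. Consequently,
near-perfect synthetic cross-validation accuracy demonstrates that the
pipeline's plumbing and estimators are correct — not that any classifier
will reach comparable accuracy on real material, where annotation bias
toward easy pixels, organ-boundary mixtures and midrib misclassification
all reduce it. Similarly, planted-QTL recovery shows the trait→scan chain
is statistically sound at large effect sizes, not that real image-derived
traits will yield associations. Known limitations, in addition: QDA's
posterior is computed from ridge-regularized covariances (a calibrated
approximation, not MASS's exact QDA); the MLP uses plain SGD without
early stopping; and the mixed-model scan is single-marker, so its power
profile differs from multi-locus methods on polygenic architectures.
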
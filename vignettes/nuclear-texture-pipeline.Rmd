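---
title: "Nuclear chromatin texture analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear chromatin texture analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Senescent cells remodel their nuclei: nuclear area grows and chromatin
texture coarsens and homogenizes. These changes are visible in
DNA-counterstained microscopy and can be quantified without any staining
beyond the DNA dye, which makes nuclear morphology an attractive
label-free readout for classifying cells as proliferating-like or
senescent-like — for example to ask whether drug-treated cells have
entered a senescence-like state.

`senotex` implements the full analysis chain for this readout as it is
run on automated microscopes: tiled overview acquisition, stitching by
stage coordinates, nucleus detection, per-nucleus foreground
segmentation, grey-level co-occurrence matrix (GLCM) texture features,
machine-learning quality control of the automatically acquired images,
and classification of treated cells against proliferating and senescent
reference classes. Because the pipeline's correctness claims must be
testable without access to microscope data, the package ships a
synthetic scene generator that produces every input the pipeline
consumes, with exact ground truth.

# The synthetic generator

A nucleus is modelled as an ellipse whose interior intensity is

* a band-limited Gaussian random field — white noise smoothed with a
  Gaussian of width `texture_corr_len_px` and re-standardized — scaled to
  ±15% of the interior level (the chromatin "grain"); plus
* hard-disk foci of radius 2 px with additive contrast `foci_contrast`,
  Poisson-placed with density `foci_density` per µm² (heterochromatin
  puncta); over
* a constant interior level of 0.55 and background of 0.05, with
  Gaussian read-out noise (`noise_sd = 0.02`) added everywhere.

The texture model was chosen because GLCM statistics respond smoothly
and monotonically to its correlation length, so ordinal claims
("senescent texture is smoother") can be enforced and tested by
construction. It does **not** reproduce the real spatial organisation of
chromatin (nucleoli, lamina-associated rims, replication foci), photon
(Poisson) noise statistics, a microscope PSF, or staining-intensity
batch effects. Passing tests therefore demonstrate that the *pipeline
machinery* is correct and that the models recover differences the
generator encodes — not that the classifiers would reach the same
accuracy on real micrographs. The real-data analogue of this pipeline in
fact found STED-scale texture to be dominated by staining variation
between replicates; the package mirrors the procedure, not that
data-dependent outcome.

Default condition parameters (chosen once, as ordinal re-enactments of
the observed senescence phenotype — larger nuclei, longer-range and more
homogeneous texture, fewer/weaker puncta):

| condition      | area (px², mean ± sd) | corr. length (px) | foci /µm² | foci contrast |
|----------------|----------------------|-------------------|-----------|---------------|
| proliferating  | 7000 ± 700           | 1.5               | 8         | 0.25          |
| treated_d3     | 9500 ± 900           | 2.25              | 6         | 0.20          |
| senescent, treated_d6/d9 | 12000 ± 1100 | 3.0             | 4         | 0.15          |

The ~1.7× area increase matches the direction and rough magnitude of
senescent nuclear enlargement; the 3-day treatment sits midway, and 6/9
days equal the senescent state. Absolute values are conventions — only
the ordering is a tested contract. Pixel sizes default to 25 nm
(detail/STED profile) and 100 nm (overview/confocal profile), which are
conventional for these modalities rather than measured values.

Bad images are generated in five labelled failure modes mirroring what
automated acquisition produces: out-of-focus frames (σ = 8 px blur),
border-truncated nuclei, blank-row scanner artifacts (≥ 12% of rows set
to exact 0, as when the stage leaves the field of view), empty frames,
and doublets. The number of bad images is `round(bad_fraction × n_good)`
with `bad_fraction = 0.2` by default.

All randomness flows from one integer master seed through a
counter-based splitting scheme (`split_seed()`), so every image, stage
and model draws from its own reproducible sub-stream and any stage can
be re-run independently with identical results.

# Segmentation

**Overview detection.** Tiles are maximum-projected, placed at the
integer pixel offset nearest their stage coordinates, and fused by
per-pixel mean in overlaps. Nuclei are then detected by k-means
clustering of per-pixel features (raw intensity, Gaussian-filtered
intensity, Sobel gradient magnitude), taking the cluster with the
highest mean raw intensity as foreground, eroding with a radius-3 disc,
and labelling 8-connected components. Open choices and how they were
fixed:

* `k = 2` clusters; foreground = highest-mean-intensity cluster. A
  config option allows `k > 2` with the same foreground rule.
* Feature blur σ = 2 px: small enough not to merge adjacent nuclei at
  the default pixel size, large enough to suppress single-pixel noise.
* Features are z-scored before clustering so no single response
  dominates the Euclidean metric.
* k-means runs with a fixed seed and 10 restarts (best inertia), making
  detection deterministic.
* Components smaller than the erosion footprint (37 px for radius 3)
  are dropped after erosion. The filter-response features dilate any
  bright object by a pixel or two, so a detection smaller than the
  structuring element erodes to a few-pixel core instead of vanishing;
  removing sub-footprint remnants implements what the erosion step is
  for — discarding small background detections.

**Detail-image foreground.** Intensities are normalized to the
(0.025, 0.995) quantiles and clipped to [0, 1]; a strongly blurred
(σ = 16 px) version is thresholded with Li's minimum-cross-entropy
threshold (implemented in-package as the Li–Tam fixed-point iteration;
it matches `scikit-image.filters.threshold_li` to ~1e-7 on shared
inputs); objects strictly smaller than 512 px are removed and holes
strictly smaller than 512 px are filled. Removal precedes hole filling
by default; the order is config-exposed and tested both ways. Foreground
objects are 8-connected and holes 4-connected (the topological dual).

Two numerical guards handle degenerate frames:

* constant images (no quantile spread) return an empty mask flagged
  `degenerate`;
* frames whose *blurred* normalized range is below 0.2 are treated as
  signal-free. Quantile normalization is gain-invariant, so a pure-noise
  empty frame is stretched to full range and would otherwise segment
  arbitrary blobs; after the σ = 16 blur, pure noise retains a range of
  roughly 0.1 while any frame containing a nucleus spans more than 0.4,
  and 0.2 separates the regimes.

**Accuracy regime.** Li thresholding of a strongly blurred image places
the boundary below the half-maximum of the smoothed edge, dilating the
mask by roughly σ when the background dominates the frame. The mask is
consequently accurate (IoU ≥ 0.9 against ground truth) when the nucleus
fills ≳ 50% of the frame — which is the geometry of a real detail
acquisition, taken centred on a detected nucleus — and systematically
generous for small nuclei in large frames. Segmentation-accuracy tests
therefore use radius-100 px nuclei in 240 × 240 frames; the feature
tests tolerate the dilation because all conditions share it.

# Texture features

Within the foreground mask, grey-level co-occurrence matrices are
computed at distances {2, 4, 7, 12, 16} px (detail profile) or
{2, 4, 8, 16} px (overview profile) and angles {0, π/2}, after a light
σ = 0.5 px blur of the normalized image. Six statistics summarize each
(distance, angle) slice: contrast, dissimilarity, homogeneity, energy,
correlation and ASM. Implementation contracts:

* θ = 0 pairs a pixel with the one `d` columns to its right; θ = π/2
  with the one `d` rows below.
* Both endpoints of a pair must lie inside the mask (the strictest
  reading of "within the foreground area").
* Matrices are symmetric (both pair orders counted) and normalized to
  sum to 1; quantization uses 64 levels via `floor(v × 64)` with 1.0
  mapped to level 63. Neither the level count nor the symmetric/normed
  flags are dictated by the recipe this follows, so absolute feature
  values are implementation-relative; ordinal behaviour across
  conditions is the tested contract.
* Correlation of a slice whose marginal variance vanishes (all mass on
  one level) is defined as 1.
* A slice with no valid pair yields `NA` for all six statistics — a
  missing-feature sentinel that is median-imputed from training data
  before any model sees it, never a silent zero.

The detail ("STED") profile emits 70 features per nucleus: 60 GLCM
values plus mean foreground intensity (raw and normalized), foreground
sd, segmented area, the two raw quantile values used in normalization,
image width/height and the number of all-zero rows and columns (counted
on the raw image). The overview ("confocal") profile emits 48 GLCM
values plus area, eccentricity and mean intensity. Image size and
blank-row/column counts are *auxiliary*: the QC classifier uses them
(they flag scanner artifacts) but the embedding and condition classifier
exclude them.

# Quality control and classification

**QC.** A 500-tree random forest is trained on standardized full feature
vectors of labelled good/bad images. Stratified 5-fold cross-validation
yields out-of-fold good-class probabilities, and the decision threshold
is the smallest probability whose out-of-fold precision for the good
class — TP/(TP + FP) — reaches the 0.95 target. Two details:

* A candidate threshold must retain at least 20 out-of-fold predictions.
  Without this, a single top-scored good image would certify any target,
  and label-shuffled data would pass calibration about half the time.
* If no threshold qualifies, a reject-all sentinel (> 1) is stored and a
  warning raised — calibration failure is loud, not silent.

The recipe this re-implements describes its target as "precision
(true-positive rate)"; precision and TPR are different quantities, and
precision is what is implemented and tested here.

**Condition model.** An RBF-kernel SVM (C = 1) on standardized
non-auxiliary features of the two reference classes; treated cells never
enter training and are scored per cell, reporting per-group fractions
classified proliferating-like vs senescent-like. A group is called
ambiguous when neither fraction reaches 0.7 (the source recipe gives no
numeric rule; 0.7 is this package's convention). With the default
generators the 3-day-treated group classifies mostly senescent-like but
strictly between the reference extremes — the ordinal pattern, not the
exact fractions, is the contract. t-SNE embeddings (perplexity 30, fixed
seed) are produced for visual reporting only and never feed
classification.

**Leakage rules.** Standardization statistics, imputation medians and
the QC threshold are all computed from training data only and reused
unchanged on held-out data; tests assert this by refitting on disjoint
halves.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale: QC calibration uses 500 good + 500 bad training
images with an equal-sized independent test set; end-to-end condition
recovery uses 40 reference cells per class with 50-cell treated groups
over 5 seeds; segmentation accuracy uses 20 radius-100 nuclei; the GLCM
implementation is checked against a pair-enumeration oracle on 100
random 16 × 16 masked images. These sizes were chosen so the whole suite
runs on a laptop core in minutes while keeping every binomial margin
meaningful.

# Known limitations

* The generator's realism limits are listed above; in particular, no
  claim is made about classifier accuracy on real micrographs.
* Overview detection is used for both detection and instance masks;
  touching nuclei are not split, and 3D segmentation is out of scope.
* Stage coordinates are trusted exactly (no global registration
  refinement); stitching fuses overlaps by per-pixel mean.
* Only the six listed GLCM statistics are computed; no
  rotation-invariant averaging across angles.
* The QC threshold transfers to populations whose class balance matches
  the calibration set; under strong prevalence shift the achieved
  precision will differ.
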
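# senotex

Automated nuclear-morphology analysis for senescence phenotyping.

Senescent cells enlarge their nuclei and remodel chromatin texture, and
both changes are visible in DNA-counterstained microscopy. `senotex`
implements the full analysis chain that turns tiled microscope
acquisitions into per-cell phenotype calls:

1. **Simulation** — a synthetic generator of tiled overview z-stacks and
   single-nucleus detail images with condition-dependent nuclear size
   and chromatin texture, plus labelled bad-image failure modes, so the
   whole pipeline is testable with exact ground truth.
2. **Stitching & detection** — tiles are maximum-projected, placed by
   stage coordinates (overlaps fused by mean), and nuclei detected by
   k-means clustering of per-pixel intensity/Gaussian/Sobel features
   followed by binary erosion of radius 3.
3. **Segmentation** — detail images are normalized to the
   (0.025, 0.995) intensity quantiles and the nuclear foreground is
   segmented by Li (minimum-cross-entropy) thresholding of a strongly
   blurred (σ = 16 px) copy, removing objects < 512 px and filling
   holes < 512 px.
4. **Texture features** — grey-level co-occurrence matrices within the
   foreground at distances {2, 4, 7, 12, 16} px (detail profile;
   {2, 4, 8, 16} for overviews) and angles {0, π/2}, summarized by the
   six Haralick statistics

   contrast = Σᵢⱼ P(i,j)(i−j)², dissimilarity = Σ P(i,j)|i−j|,
   homogeneity = Σ P(i,j)/(1+(i−j)²), ASM = Σ P(i,j)², energy = √ASM,
   correlation = Σ P(i,j)(i−μᵢ)(j−μⱼ)/(σᵢσⱼ),

   plus shape, intensity and bookkeeping features (70 per nucleus in
   the detail profile).
5. **Quality control** — a random forest on the full feature vectors of
   labelled good/bad images; stratified 5-fold cross-validation selects
   the smallest probability threshold whose out-of-fold good-class
   precision, TP/(TP+FP), reaches 95%; only images passing the
   calibrated filter continue.
6. **Phenotyping** — t-SNE embedding of non-auxiliary features for
   inspection, and an RBF SVM trained on proliferating vs senescent
   reference cells, applied per cell to treated groups to report the
   fraction classified senescent-like.

See `vignettes/nuclear-texture-pipeline.Rmd` for the model, parameter
rationale, numerical guards and known limitations.

## Worked example

The `analysis/` directory holds the numbered stage drivers
(`01_simulate.R` … `05_classify.R`); running them in order reproduces
the whole desk-scale study under `results/analysis/`. A condensed
version in R:

```r
library(senotex)

# simulate, stitch and detect a tiled overview with 5 planted nuclei
scene <- generate_overview_scene(5, condition_params("proliferating"),
                                 overlap_fraction = 0.2, seed = 7)
fused <- stitch_tiles(scene$tiles)
det   <- detect_nuclei_overview(fused)
det$n_objects
#> [1] 5

# segment and featurize one synthetic senescent nucleus
g   <- generate_nucleus_detail(condition_params("senescent"), seed = 1)
seg <- segment_sted_foreground(g$image)
f   <- extract_features(g$image, seg$mask, "sted")
ncol(f); f$area_px
#> [1] 70
#> [1] 14667
```

Running the staged analysis prints, among other things:

```
## Detected 5 nuclei (5 planted)
   centroid error vs truth: median 0.21 px, max 0.26 px
   calibrated threshold: 0.496 (target precision 0.95)
   kept 118/144 images; 1 truly-bad images slipped through (0.8% of kept)
## Treated-group classification:
   treated_d3  n= 29  senescent-like 0.86  -> senescent
   treated_d6  n= 30  senescent-like 1.00  -> senescent
## Per-condition summaries (median area in px):
   proliferating median 10964  IQR [10389, 11409]  n=28
   senescent     median 15185  IQR [14476, 15969]  n=31
```

i.e. every planted nucleus is recovered with sub-pixel centroid error,
the calibrated QC filter keeps contamination below its 5% budget, and
treated groups order between the proliferating and senescent references
(day 3 intermediate, day 6 fully senescent-like), with the senescent
median nuclear area ~1.4× the proliferating one after segmentation.

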
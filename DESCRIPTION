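Package: senotex
Title: Nuclear Chromatin Texture Analysis for Senescence Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated nuclear-morphology analysis pipeline for
    DNA-counterstained microscopy of proliferating, senescent and
    drug-treated cells. Simulates tiled overview acquisitions and
    single-nucleus detail images with condition-dependent nuclear size and
    chromatin texture, stitches tiles by stage coordinates, detects nuclei
    by unsupervised pixel clustering, segments single-nucleus foregrounds
    by Li thresholding, extracts grey-level co-occurrence matrix (Haralick)
    texture features together with shape and intensity features, filters
    images with a precision-calibrated random-forest quality-control
    classifier, and classifies treated cells against proliferating and
    senescent references with a support-vector machine, with t-SNE
    embeddings and per-condition feature summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rtsne,
    e1071,
    jsonlite,
    randomForest,
    rhdf5,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
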
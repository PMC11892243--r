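Package: itilscore
Title: Automated Intraepithelial Tumour-Infiltrating Lymphocyte Scoring for
    H&E Colorectal Cancer Slides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automated pipeline for quantifying intraepithelial
    tumour-infiltrating lymphocytes (iTILs) in haematoxylin-and-eosin
    histology of colorectal cancer. Provides whole-slide tile planning and
    reconstruction across the three working resolutions (4, 0.5 and 0.25
    microns per pixel), Macenko stain normalisation, a Gaussian-heatmap
    point-detection codec with confidence gating and point-based
    non-maximum suppression, pluggable segmentation/detection backends with
    deterministic reference implementations, high-power-field-equivalent
    square-field density scoring aggregated by the median into an AI iTIL
    score with rule-based slide flagging, distance-matched detection
    evaluation (precision/recall/F1 and average precision), and the
    survival layer (five-year censoring, Kaplan-Meier with log-rank, Cox
    proportional hazards, grouped cut-off search, Stage II clinical risk)
    used to derive and apply the 17 iTILs per square millimetre tumour
    cut-off. A synthetic-slide and synthetic-cohort generator with known
    ground truth supports end-to-end testing without whole-slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
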
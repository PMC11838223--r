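Package: nicheshift
Title: Spatial Niche Analysis for Single-Cell Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Edge-to-edge distance geometry and niche analysis for imaging-based
    single-cell spatial transcriptomics (CosMx-style field-of-view data).
    Provides ring-neighborhood enrichment testing with Poisson generalized
    linear mixed models (field of view as random effect, neighborhood size as
    offset), a permutation test for shifts in the distribution of
    nearest-tumor-cell distances between timepoints, proximity-stratified
    pseudo-bulk ligand-receptor analysis, merging and F1-at-IOU evaluation of
    nuclear and membrane instance segmentation masks, reference-profile
    likelihood cell typing with negative-probe background adjustment, and a
    synthetic multi-FOV tissue generator with planted spatial and expression
    structure for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    lme4,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
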
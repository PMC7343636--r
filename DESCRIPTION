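Package: voxcyte
Title: Imaging Biomarkers for Drug Response in 3D Bioprinted Skin Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chemotherapeutic effect in 3D bioprinted cutaneous
    squamous cell carcinoma (cSCC) skin constructs imaged by bimodal
    (reflectance + fluorescence) confocal microscopy. Provides a full
    volumetric analysis pipeline: intensity normalization for laser power
    and detector gain, rigid inter-channel registration from z-sum
    reflectance projections, 3D segmentation (Gaussian smoothing, Otsu
    binarization, 26-connected components, small-object removal),
    per-construct and per-tumor imaging biomarkers (object counts and total
    fluorescence), treatment effects as post-treatment percent of
    pre-treatment values, and group statistics (pooled two-sample t-test,
    Hedges' g with exact small-sample correction, unbalanced two-way ANOVA
    with Type III sums of squares). A synthetic phantom generator with full
    ground truth emulates the stratified-skin reflectance texture, RFP
    tumor spheroids with dark necrotic cores, sparse GFP-labeled
    keratinocytes, sensor noise, and acquisition faults, so the whole
    pipeline is testable end to end without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
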
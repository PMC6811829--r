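Package: capipe
Title: Two-Photon Calcium Imaging Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-photon calcium imaging sessions:
    rigid motion correction, correlation-based soma and bouton segmentation,
    neuropil-corrected dF/F trace extraction, population activity and
    drug-epoch statistics, and difference-of-Gaussians size-tuning fits with
    a surround-suppression index. Includes a synthetic session generator
    (donut somata, neuropil contamination, GCaMP6s-like kinetics, locomotion
    bouts, post-injection gain changes) that provides ground truth for every
    stage, so the whole pipeline is verifiable without raw imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
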
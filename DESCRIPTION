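Package: tauHCS
Title: Compartment-Specific Quantification of Tau in High-Content
    Neuronal Imaging Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation and quantification pipeline for four-channel
    high-content fluorescence images of dense human neuronal cultures,
    measuring total and phosphorylated tau separately in cell bodies and
    neurites. Includes a synthetic field generator with full ground truth,
    iterative neurite mask extraction with minor-segment testing and
    directional gap closing, exclusion of dead nuclei and cell clumps,
    plate-level quality control, DMSO normalization, Z'-factor assay
    quality statistics, hit calling with neurotoxicity flagging, and
    four-parameter logistic dose-response fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    methods,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
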
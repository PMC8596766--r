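Package: qt2map
Title: Quantitative MRI T2 Mapping of Cartilage Repair Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rician-noise-corrected per-voxel T2 estimation from multi-echo
    magnitude MRI, with automatic background noise estimation, fit-quality
    filtering, volume-of-interest T2 distribution analysis, quartile-derived
    tissue thresholds, three-class tissue composition quantification and
    nonparametric group comparison. Includes a synthetic multi-echo ankle
    phantom generator with known ground truth for validation, and NIfTI, CSV
    and JSON input-output for pipeline use on clinical multi-echo series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
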
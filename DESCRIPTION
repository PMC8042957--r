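Package: microBIC
Title: Bone-to-Implant Contact Quantification from 2D Micro-CT Slices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies implant osseointegration from reconstructed micro-CT
    volumes of threaded implants in bone. Extracts longitudinal slices through
    the implant axis at several angles (0/45/90/135 degrees), segments each
    slice into background, bone and implant by windowed thresholding, excludes
    an interface voxel layer to suppress metal artifacts, and measures the
    bone-to-implant contact ratio (BIC) groove by groove along the thread
    profile. Includes a synthetic phantom generator with analytic ground-truth
    BIC for validation, and paired-comparison / correlation statistics for
    agreement between modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
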
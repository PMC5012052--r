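Package: osic
Title: Optimal Safe Implantation Corridor Planning from 3D Landmark Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated three-dimensional pre-surgical planning of vertebral
    optimal safe implantation corridors (OSICs) for canine atlantoaxial
    stabilization. From labelled 3D region-of-interest points exported from a
    DICOM viewer, the package builds per-vertebra anatomical coordinate frames,
    computes projected implant angles (ProjA), safety-margin angles (SafA),
    corridor widths and implant lengths, and provides the method-comparison
    statistics (Lin's concordance correlation, Bland-Altman bias, normal
    tolerance intervals, absolute-error summaries) used to validate the method
    against manual on-screen measurements. A synthetic scene generator with
    known ground-truth angles supports landmark-placement error simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
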
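Package: ctmotion
Title: CT-Based Radiostereometric Analysis of Implant Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures micromotion of a tibial knee implant relative to the
    tibia from paired CT volumes, in the manner of CT-based radiostereometric
    analysis (CT-RSA). Provides threshold/region-growing/morphology mask
    segmentation of bone and implant, masked voxel-intensity rigid
    registration between baseline and follow-up scans, migration parameters
    in the implant-centred anatomical frame (MTPM, translations, rotations,
    total translation and total rotation), Bland-Altman limits of agreement
    with confidence intervals and intraclass correlation for method and
    observer comparisons, and a digital tibia-plus-tibial-tray phantom
    generator with known ground-truth micromotion for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
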
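Package: fpmorph
Title: Femoropopliteal Artery Morphometry Under Knee Flexion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Centerline-based morphometry of the femoropopliteal arterial
    segment under knee flexion: synthetic limb phantoms with analytically
    known ground truth, medialness-weighted centerline extraction from binary
    masks, length/tortuosity/equivalent-diameter measurement with splitting
    at the adductor hiatus, rigid bone-based ICP registration, decomposition
    of tortuosity onto antero-posterior and lateral anatomical planes derived
    from the tibia axis, and the paired statistics comparing straight- versus
    bent-knee and pre- versus post-stenting configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    nortest,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
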
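Package: canaliq
Title: Automated Quantification of Membrane Protein Translocation in
    Canalicular Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toponomic analysis of two-channel confocal fluorescence images
    of bile canaliculi. Detects canalicular membrane fragments in a
    structural-marker channel (e.g. Zo-1) by supervised texture
    classification, thins them to centerlines with an
    Euler-characteristic-preserving skeletonization, extracts densitometric
    intensity profiles orthogonal to the membrane, selects and ranks
    profiles by peak-symmetry and contrast criteria, centers them against a
    model profile, and summarises the functional-marker distribution (e.g.
    Bsep) with zone-based descriptors. Includes a synthetic image generator
    with ground truth, unpaired rank-sum comparison of conditions with
    repeated subsampling, and a density-crossing threshold classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
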
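Package: olcn
Title: Quantification of Osteocyte Lacunar-Canalicular Network Integration
    Across Bone Remodeling Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how the osteocyte lacunar-canalicular network
    (OLCN) integrates across bone remodeling interfaces in nano-CT gray-value
    volumes. Implements regional mineralization assessment from interpolated
    remodeling-region masks (normalized mean gray value and tissue-age
    ranking), projected canalicular porosity from minimum-intensity
    projections with top-hat segmentation (pCan.P), and per-lacuna counting
    of canalicular connections crossing the cement-line interface (N.Conn),
    together with a synthetic bone-phantom generator that supplies full
    ground truth for validating every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
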
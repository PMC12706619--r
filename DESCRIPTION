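Package: evansindex
Title: Automated Evans Index Measurement from Ventricle and Skull Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the Evans Index (the ratio of maximal
    frontal-horn width to maximal inner-skull diameter at the same axial
    level) from NIfTI label volumes of the lateral ventricles and the
    intracranial volume, given anterior commissure (AC), posterior
    commissure (PC) and interventricular foramen (IVF) landmarks. Provides
    AC-PC rigid realignment, binary-mask postprocessing (spurious-cluster
    removal, internal-void filling), frontal-horn extraction anterior to
    the IVF, width and diameter measurement with an edge-to-edge
    convention, rotational-robustness protocols (pitch, yaw, roll
    perturbations in corrected and blind modes), Bland-Altman agreement
    statistics with an exact Wilcoxon signed-rank test, and a synthetic
    head-phantom generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
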
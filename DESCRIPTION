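Package: dosewarpqa
Title: Ground-Truth Validation of Deformable Dose Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A validation framework for deformable dose accumulation in
    online adaptive radiotherapy. Generates a synthetic pelvic phantom
    (CT, structure set, plan-like fraction dose), authors known invertible
    organ deformation fields, synthesizes deformed treatment images, and
    accumulates fraction dose back to the planning anatomy both through a
    registration under test and through the inverse of the known true
    field. Accumulation error is quantified by 3-D gamma analysis,
    per-structure displacement statistics, dose-volume-histogram clinical
    goal adherence and discrepancy counts, and Dice/Hausdorff contour
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
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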
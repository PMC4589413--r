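Package: vmhc
Title: Voxel-Mirrored Homotopic Connectivity with Cluster-Extent Inference
Version: 0.1.0
Authors@R: person("VMHC", "Maintainers", email = "vmhc@example.org", role = c("aut", "cre"))
Description: Tools for interhemispheric functional-symmetry analysis of 4D
    brain time-series volumes: polynomial template symmetrization by
    homotopic mean-squared-error minimization, voxel-mirrored homotopic
    correlation maps with autocorrelation-corrected Fisher-z inference,
    two-group contrasts calibrated by Monte-Carlo cluster-size
    distributions built from phase-scrambled surrogates, and relative
    corpus-callosum volume statistics.  A synthetic-data module generates
    mirror-symmetric templates, homotopically correlated AR(1) time
    series and callosal-volume tables with known ground truth, so the
    whole pipeline can be exercised end-to-end without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
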
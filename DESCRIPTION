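Package: clremodel
Title: Inference of Steady-State Cardiolipin Remodeling Mechanisms from
    Lipidomic Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers acyl-chain remodeling mechanisms of the mitochondrial
    phospholipid cardiolipin (CL) from class-resolved shotgun-lipidomics
    concentration tables. Fits per-position fatty-acid distributions to
    observed CL mass-peak profiles under independent-and-identical (IID)
    and independent-and-differential (IDD) position models by
    simplex-constrained least squares, deconvolves the CL fatty-acid
    composition into contributions from acyl donor classes (PC sn-2,
    PE sn-2, PG, acyl CoA) by constrained linear regression, and assesses
    fits with four-fold cross-validation, label-permutation and
    donor-permutation significance tests, cross-sample residual analysis
    with hierarchical clustering, and a dynamic-model steady-state
    consistency check. Includes a synthetic-data generator with known
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Lipidomics, MassSpectrometry, Metabolomics, Regression,
    Software
RoxygenNote: 7.3.3
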
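Package: neurostates
Title: Neural State Segmentation and Boundary Overlap Analysis for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects neural state boundaries in multi-voxel fMRI time series
    with a greedy state boundary search (GSBS) that places one or two
    boundaries per iteration, fine-tunes boundary locations in order of
    boundary strength, and selects the number of states by maximizing the
    t-distance between within-state and consecutive-state timepoint
    correlations. Includes temporal preprocessing (high-pass filtering,
    canonical double-gamma HRF construction, Wiener deconvolution, group
    averaging), boundary-overlap statistics that compare neural state
    boundaries with perceived event boundaries and across brain regions
    (expected, absolute and relative overlap, strength and co-occurrence
    weighting, shared/unique decomposition), spherical searchlight mapping
    over NIfTI volumes, consensus network partitioning of boundary-overlap
    matrices with signed modularity, group-level inference with exact
    Wilcoxon signed-rank tests and Benjamini-Hochberg FDR, and a synthetic
    data generator with planted, optionally nested state boundaries for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
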
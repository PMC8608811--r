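Package: intpipe
Title: Intrinsic Neural Timescale Mapping and Case-Control Inference for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("intpipe", "developers", email = "intpipe@example.org",
           role = c("aut", "cre"))
Description: Estimates per-voxel intrinsic neural timescales (INT) from
    resting-state BOLD time series by summing the leading positive values of
    the sample autocorrelation function and scaling by the repetition time.
    Provides mass-univariate case-control t-mapping with connected-component
    cluster extraction, region-of-interest mean extraction, framewise
    displacement computation with a two-phase greedy motion-matching
    algorithm, ROI-level inference (Welch t, Hedges g, Bonferroni, Pearson
    correlations, additive ANCOVA main effects, 2x2 chi-squared balance
    tests), a seeded synthetic AR(1) cohort generator with planted
    case-control timescale reductions, and a config-driven pipeline that
    orchestrates discovery, replication, and motion-matched reanalysis.
    Includes a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
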
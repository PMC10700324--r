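Package: corrtf
Title: Correlation Transfer Function Connectivity for Longitudinal
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Directed functional connectivity analysis for longitudinal
    resting-state fMRI cohorts. Computes the correlation transfer function
    (CorrTF), the in-band magnitude ratio of the discrete Fourier transforms
    of two region-of-interest mean time series, across the 116 regions of
    the AAL atlas, and screens every directed connection for longitudinal
    change across three visits with a two-stage procedure (paired t-tests on
    both visit transitions intersected with a one-way ANOVA over visits).
    Includes a Pearson correlation with Fisher z-transform comparison arm,
    region- and network-level summaries of significant connections, a
    seeded synthetic cohort generator with injectable directed effects, and
    ingestion of preprocessed 4D NIfTI volumes with an integer-labeled
    atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
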
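Package: connectopy
Title: Connectopic Mapping of Cortical Regions with Trend-Surface Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates smoothly varying connection topographies
    ("connectopies") of a cortical region of interest from 4D fMRI data
    using connectivity fingerprints, eta-squared similarity and Laplacian
    eigenmaps; summarises them with polynomial trend-surface models selected
    by BIC; projects them onto the whole brain by dual regression; and runs
    covariate-adjusted association and group-comparison statistics with
    Holm family-wise error control. Includes a synthetic fMRI phantom
    generator with a planted gradient and a planted gradient-flatness to
    behaviour coupling, so that every stage of the pipeline can be
    validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
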
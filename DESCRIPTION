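Package: qser
Title: Quantitative Structure-Economy Relationships for Commercial
    Chemical Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating molecular descriptors to market prices
    across large commercial compound catalogues. Computes formula-level
    descriptors (average and nominal molecular weight, atom counts,
    nitrogen-rule parity), converts weight-based prices ($/g) to
    molar-based prices ($/mol), summarises descriptors and prices in
    fixed-width molecular-weight bins, estimates record-level and
    bin-level Pearson correlations, and calibrates their credibility
    with seeded Monte-Carlo nulls (i.i.d. random variates and shuffled
    prices). Includes heteroatom sub-library and nominal-mass parity
    analyses, readers for SDF (V2000) and delimited catalogues, and a
    calibrated synthetic catalogue generator for end-to-end testing
    without vendor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
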
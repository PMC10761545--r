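Package: hcpurity
Title: Label-Free Quantification of Host Cell Protein Impurity in Purified Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the mass fraction of host-cell-protein (HCP) impurity in
    a purified recombinant protein from protein-level MS1 intensity tables.
    Summed host-to-target MS1 intensity ratios are calibrated against
    gravimetric spike-in series of a host proteome (or a defined protein mix),
    the calibration line is inverted to predict unknown impurity mass
    fractions with a full inverse-prediction uncertainty budget, and the
    impurity is converted to a purity value with asymmetric confidence
    intervals. Includes leave-one-out cross-validation and pooling of
    calibrations across calibrant sources, co-purified-protein profile
    analysis with unscaled PCA biplots, a top-N capture/bias analysis, a
    protein-subsampling error simulation, and a synthetic LFQ data generator
    for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
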
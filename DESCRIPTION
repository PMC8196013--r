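Package: xlinkfdr
Title: Multi-Level False Discovery Rate Estimation for Crosslinking Mass
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-decoy false discovery rate (FDR) estimation for
    crosslinking mass spectrometry, from crosslink-spectrum matches (CSMs)
    up to protein-protein interactions (PPIs). Implements separate handling
    of self and heteromeric crosslinks, root-sum-square score aggregation
    across identification levels, cascaded lower-level thresholds, local-FDR
    score normalisation and multi-dataset merging, decoy database generation
    by sequence reversal with enzyme-site swapping, and independent error
    controls (entrapment databases with lysine/arginine search-space
    normalisation, non-crosslinkable pairs from size-exclusion coelution
    profiles, wrong-crosslinker accounting). A synthetic benchmark generator
    with known ground truth makes the estimator's calibration testable end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
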
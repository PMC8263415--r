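Package: striasig
Title: Striated Tool-Mark Signature Comparison by Normalized Cross-Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational comparison of striated tool marks from
    3D surface topography: reading and validating regular-grid height maps,
    simulating striated marks with known ground truth, extracting and
    normalizing 1D surface signatures (moving-average detrending, zero-phase
    low-pass and band-pass filtering, outlier removal), aligning and scoring
    signatures by normalized cross-correlation, counting consecutive matching
    striae (CMS), and classifying similarity scores against known-match /
    known-non-match reference distributions with 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
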
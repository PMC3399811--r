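Package: tagcna
Title: Significant Consensus Copy-Number Events via Tag Markers and
    Peel-Off Permutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies significant consensus copy-number events (SCEs)
    across a cohort of tumour samples from segmented log2-ratio profiles.
    Adjacent markers are grouped into correlation blocks with a circular
    binary segmentation changepoint engine, one tag marker per block is
    scored by the summed aberration magnitude across subjects, and
    family-wise significance is assessed with an iterative peel-off max-T
    permutation scheme that converges toward a background-only null
    distribution.  Includes a tumour/normal mixture simulator with
    embedded ground-truth events, background-only null cohorts and
    contamination sweeps, plus evaluation utilities (marker-level ROC,
    empirical type-I error, detection power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
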
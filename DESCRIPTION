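Package: polyafrac
Title: Poly(A) Tail Fractionation RNA-Seq Analysis and Co-IP Enrichment
    Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transcripts polyadenylated by a poly(A) polymerase
    of interest from oligo-dT tail-length fractionation RNA-seq. Computes
    per-transcript polyadenylation ratios (long-fraction enrichment in the
    active-enzyme condition relative to a catalytically dead control), fits
    a robust normal null to the log-ratio distribution and calls outlier
    transcripts under Benjamini-Hochberg false discovery control. Ships a
    synthetic fractionation-experiment generator with known ground truth,
    hit-set concordance and 3'-UTR feature-bias tests, k-mer enrichment of
    hit UTRs, and label-free quantification (LFQ) enrichment scoring for
    co-immunoprecipitation mass spectrometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
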
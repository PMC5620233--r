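Package: ctcwga
Title: Somatic Mutation Detection in Whole-Genome-Amplified Circulating
    Tumor Cell DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for calling somatic mutations in
    whole-genome-amplified (WGA) circulating-tumor-cell (CTC) DNA from
    targeted amplicon panel sequencing. WGA of nanogram DNA inputs
    introduces artifactual low-frequency variants, both recurrent across
    independently amplified samples and random; this package characterizes
    those artifacts from amplified normal-tissue controls, builds a
    recurrent-error blacklist, applies allele-frequency thresholding and
    tumor-matched intersection to CTC variant calls, and screens
    CTC-private calls by dual-WGA replicate concordance. Downstream
    analyses include the strand-collapsed six-class mutation spectrum,
    per-gene alteration tabulation, and rank-based association of CTC
    mutation allele frequencies with clinical variables (CEA, Dukes'
    stage, MSI status, age). A calibrated synthetic-cohort generator
    emulates the amplicon panel, the WGA error process, tumor spike-in
    at latent tumor fractions, overlapping amplicon read pairs, and
    clinical records, so the whole cascade is testable end to end.
    Includes the two bespoke read-level refinements for short amplicons
    sequenced with overlapping mates: overlap-aware base-quality
    adjustment and 5' primer trimming with a mismatch allowance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
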
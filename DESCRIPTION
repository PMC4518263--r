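Package: ernatools
Title: Enhancer RNA State Calling and Cross-Tissue Target Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls the transcription state of intergenic enhancers from
    strand-aware RNA-seq contigs (an enhancer is transcribing when a contig's
    5' start falls within 3 kb of the enhancer locus), quantifies eRNA-target
    expression correlation in BPKM against matched flanking, gene-upstream and
    random-intergenic backgrounds, compares target-gene expression of
    transcribing versus non-transcribing enhancers across tissues via
    same-positioned enhancer groups (z-scored BPKM, paired t and one-sided
    rank-sum tests, least-rectangles regression), tests ncRNA-family annotation
    enrichment against length-matched random intergenic controls with a pooled
    two-proportion z-test, and discovers miRNA-like promoter target sites
    (8mer/7mer-m8/7mer-A1 seed sites and a position-weighted complementarity
    score) with a shuffle-bootstrap null. A synthetic-data module generates
    multi-tissue worlds with planted effects so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
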
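Package: mircascade
Title: miRNA-Centered Regulatory Network Analysis from Small RNA, Degradome
    and Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, stage-tested implementation of a plant
    miRNA-centered regulatory-network analysis: cleaning and mapping of
    small-RNA reads, criteria-based annotation of miRNA hairpin loci,
    conservation and family classification, genomic clusters and synteny
    anchoring, miRNA target prediction with expectation-penalty and
    duplex-energy-ratio scoring, degradome (PARE) cleavage-category
    confirmation, RPM/FPKM quantification and expression-pattern
    classification, miRNA-target correlation statistics, weighted
    co-expression modules with eigengenes and kME hubs, promoter PWM
    scanning, and enumeration of TF-miRNA-target cascade and
    feed-forward-loop motifs. A fully specified synthetic-data generator
    with machine-checkable truth tables makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
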
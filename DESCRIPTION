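Package: ribodens
Title: Differential Ribosome Density and Translation Initiation Site Analysis
    for Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ribosome profiling experiments that probe
    translational control under integrated-stress-response conditions.
    Partitions footprint 5'-end coverage into 5'UTR/CDS/3'UTR region counts,
    tests differential ribosome density with a negative-binomial
    condition-by-assay interaction model (CPM normalisation, read filters,
    dispersion shrinkage, likelihood-ratio tests, Benjamini-Hochberg FDR),
    calls translation initiation sites from harringtonine-stabilised
    footprints with rule-based peak detection and start-codon assignment,
    tests condition-dependent switching between initiation sites, classifies
    upstream and internal open reading frames, and ships a synthetic
    footprint generator emulating a 3-replicate, 2-condition design with
    RNA-seq, cycloheximide- and harringtonine-stabilised libraries so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
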
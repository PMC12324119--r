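Package: methconcord
Title: Cross-Platform CpG Methylation Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Methconcord", "Developers", email = "methconcord@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing per-CpG 5-methylcytosine calls between two
    detection platforms, such as PacBio HiFi long-read sequencing and
    whole-genome bisulfite sequencing (WGBS). Reads bedMethyl and Bismark
    coverage call files into a common record model, builds sequence-level
    (CpG island/shore/shelf, GC density, repeat class) and functional
    (gene feature, regulatory) genomic-context catalogs, classifies
    methylated CpGs under level and depth thresholds, decomposes the two
    platforms' methylated-CpG sets with per-site discordance explanations,
    computes context-stratified and depth-stratified Pearson concordance,
    performs site-level depth-matched hypergeometric downsampling,
    produces gene-aligned metagene methylation profiles, and estimates
    sequence entropy and bisulfite conversion efficiency. Includes a
    synthetic two-platform data generator so the whole pipeline runs and
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
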
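Package: BACtrace
Title: Mapping BAC Transgene Insertion Sites from Linkage, Read-Pair
    Evidence and Copy-Number Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Locates the genomic insertion site of a BAC-derived transgene
    and characterizes its consequences. Provides two-point linkage analysis
    (recombination frequency, genetic distance, LOD scores), a desk-scale
    paired-end read simulator over a synthetic diploid genome carrying a
    promoter-swapped transgene cassette with known truth, a seed-and-extend
    read mapper with split-read support, clustering of discordant-pair and
    split-read evidence into inter-chromosomal adjacency calls, per-gene
    copy-number estimation from genomic read coverage (length-normalized
    TPM against a genome-average baseline) and from droplet digital PCR
    droplet counts via Poisson inversion, and efficiency-corrected relative
    quantification of qPCR Cq data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
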
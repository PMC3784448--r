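Package: xenopart
Title: Species-of-Origin Read Partitioning for Xenograft Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions paired-end sequencing fragments from xenograft
    samples into graft-specific, host-specific, common and unmapped sets by
    comparing read identities across alignments to the graft and host
    reference genomes, then quantifies graft- and host-specific expression
    (fragment counts and RPKM over exon models) and post-processes somatic
    variant calls (hard filters including Fisher strand bias and SNP-cluster
    flags, germline subtraction, known/novel annotation, mutation spectrum,
    allele-frequency rescue classification and a host-contamination window
    check). Ships a deterministic synthetic-xenograft simulator (homologous
    genome pairs, mixed-species read libraries with truth labels, gene
    models, subclonal spike-in variants) and a seed-and-extend micro-aligner
    so the complete workflow runs end-to-end on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
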
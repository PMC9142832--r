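Package: genomesurvey
Title: Genome Survey Sequencing: K-mer Spectrum Estimates, Microsatellite
    Mining and Mitogenome Gene Order
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for low-coverage genome survey sequencing (GSS) analyses
    of non-model organisms. Counts canonical k-mers from short reads and
    estimates haploid genome size, heterozygosity and repeat content from
    the depth spectrum; computes FASTQ quality statistics (Q20/Q30, GC,
    per-position base content) and assembly contig statistics (N50/N90);
    mines perfect and compound microsatellites with MISA-compatible
    thresholds and standardizes motifs into rotation/reverse-complement
    classes; analyses mitogenome base composition and detects gene-order
    rearrangements against the canonical vertebrate mitochondrial order.
    Includes a diploid read simulator with planted SSRs and full ground
    truth so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
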
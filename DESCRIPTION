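Package: gymnotools
Title: Repeat Dating, WGD Detection, Methylome Statistics and HGT Screening
    for Giant Gymnosperm Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for the computational layer of a gymnosperm
    genome project: long terminal repeat (LTR) retrotransposon insertion-time
    dating with the Kimura two-parameter distance, Gaussian-mixture analysis
    of synonymous-substitution (Ks) distributions to locate whole-genome
    duplication signatures, whole-genome bisulfite sequencing statistics
    (lambda-based conversion-rate estimation, binomial methylation calling
    with FDR control, windowed and gene-centred methylation levels,
    demethylation-valley discovery), an average-bitscore screen for
    horizontally transferred genes over three BLAST database partitions, and
    assembly quality-control arithmetic (N50, coverage folds, QV-to-accuracy,
    telomere and centromere-monomer detection). Seeded synthetic-data
    generators produce every input the pipeline consumes together with
    ground-truth tables, so all stages can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
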
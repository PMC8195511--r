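Package: CactaScan
Title: TIR-Anchored Discovery of CACTA Transposons with Synthetic-Genome
    Validation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines genome assemblies for nonautonomous CACTA (En/Spm)
    transposons anchored on their terminal inverted repeats (TIRs): a
    degenerate 12-nt seed motif scan on both strands, extension of each hit
    to a uniform 28-nt TIR with its flanking putative 3-nt target site
    duplication (TSD), and pairing of inward-facing TIRs into element calls
    filtered by orientation, TSD identity, and a 1-30 kb span window.
    Includes TIR-family redundancy and TSD-frequency profiling, annotation
    overlap summaries, a synthetic-genome simulator with planted elements
    and ground-truth recovery scoring, insertion-allele and genotyping
    amplicon arithmetic for insertion loci, and reference-normalized
    quantification, correlation, and segregation statistics for linking
    genotypes to phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, Annotation, SequenceMatching, Transposon
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
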
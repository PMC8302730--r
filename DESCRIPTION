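Package: strainsep
Title: Strain Separation in Low-Complexity Metagenomes from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Separates conspecific bacterial strains that a long-read
    metagenome assembler has collapsed into consensus contigs.  Starting
    from a strain-oblivious assembly and position-sorted read alignments,
    the pipeline detects single-nucleotide variants, phases them into two
    haplotypes per region, partitions the reads, assembles each read set
    into haplotype contigs, and joins the resulting strain-aware contigs
    with a bi-directed scaffolding graph built from dovetail read
    alignments.  The diploid separation is iterated, guided by a Hamming
    rate stopping rule, to resolve more than two strains.  A synthetic
    strain-community generator with planted truth (variants, read origins,
    alignments) and reference-based evaluation metrics (reference
    coverage, ANI, NG50, duplication ratio) make the whole pipeline
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
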
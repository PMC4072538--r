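Package: consortiumseq
Title: Genomic Analysis of Evolved Cross-Feeding Bacterial Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing whole-genome resequencing of clonal isolates
    from experimental evolution, as arises in chemostat cross-feeding
    consortia. Implements ancestor-versus-evolved SNP calling from samtools
    pileup files with heuristic depth, allele-fraction, strand and ambiguity
    filters; mutation annotation (region, codon effect, transition/transversion
    spectrum) and multi-hit gene reports; SNP-sharing partitions and Fitch
    parsimony phylogenies of clonal isolates rooted on the ancestor; and
    Luria-Delbruck fluctuation analysis with the Ma-Sandri-Sarkar maximum
    likelihood estimator of mutation rate. A synthetic-data module generates
    annotated genomes, lineage-structured planted mutations, read pileups and
    fluctuation-assay counts with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    phangorn
Config/testthat/edition: 3
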
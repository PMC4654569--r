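Package: clonemut
Title: Reference-Free Gene-Level Mutation Analysis for Clonal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying somatic mutation accumulation in clonal
    animal populations from transcriptome data alone, without a genome
    reference. Builds intron-less "Reference Gene Model" sequences by
    linearizing an isoform assembly's contig graph, maps reads with an
    affine-gap local aligner tolerant of exon gaps, calls SNPs and InDels
    from pileups with an allelic-fraction filter tuned for clonal strains,
    classifies coding effects against six-frame ORF predictions, runs the
    codon-neutrality pseudo-SNP simulation and codon-position bias
    statistics, characterizes genomes by k-mer spectrum shape, and computes
    per-gene mutation-density and thresholded differential-expression
    summaries. Includes a synthetic clonal-transcriptome simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    Rsamtools,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
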
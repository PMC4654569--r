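#!/usr/bin/env Rscript
# Stage 7: gene-level statistics on top of the calls -- functional-category
# mutation bias (log2 high-load vs mutation-free genes) and the thresholded
# differential-expression filter chain on a null split of the read pairs.

suppressPackageStartupMessages(library(clonemut))
suppressPackageStartupMessages(library(withr))

outdir <- "results/run"
refs <- read_fasta(file.path(outdir, "gene_models.fasta"))
dens <- clonemut:::read_tsv(file.path(outdir, "snp_density.tsv"))

annotation <- simulate_annotation(setNames(nchar(refs), names(refs)),
                                  seed = 20260926)
clonemut:::write_tsv(annotation, file.path(outdir, "annotation.tsv"))

sets <- classify_mutation_load(dens, annotation)
bias <- category_bias(sets$high, sets$zero, annotation)
clonemut:::write_tsv(bias, file.path(outdir, "category_bias.tsv"))
cat(sprintf("high-load genes (>=20 SNPs/kb, >600 bp, non-transposon): %d; mutation-free: %d\n",
            length(sets$high), length(sets$zero)))
if (nrow(bias)) print(bias)

# null differential expression: split read pairs at random into two
# pseudo-libraries; with identical underlying expression nothing should
# survive the filter chain (count >= 10 in both, p < 0.001, FC >= 2)
reads <- c(read_fastq(file.path(outdir, "reads_R1.fastq")),
           read_fastq(file.path(outdir, "reads_R2.fastq")))
mapped <- map_reads(reads, refs)
aln <- mapped$alignments[!mapped$alignments$ambiguous, ]
pair_id <- sub("/[12]$", "", aln$read_id)
counts <- with_seed(20260926, {
  in_a <- unique(pair_id)[runif(length(unique(pair_id))) < 0.5]
  a <- count_reads(aln[pair_id %in% in_a, ], gene_ids = names(refs))
  b <- count_reads(aln[!(pair_id %in% in_a), ], gene_ids = names(refs))
  data.frame(gene_id = a$gene_id, count_a = a$count, count_b = b$count,
             annotated = annotation$annotated[
               match(a$gene_id, annotation$gene_id)])
})
de <- differential_expression(counts)
clonemut:::write_tsv(de, file.path(outdir, "differential_expression.tsv"))
cat(sprintf("null DE: %d of %d genes significant (expected ~0)\n",
            sum(de$significant), nrow(de)))
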
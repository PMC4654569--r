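#!/usr/bin/env Rscript
# Stage 1: generate the synthetic clonal transcriptome dataset with known
# truth -- multi-exon loci with shared exons, mutations at clonal/ancestral/
# platform-like allelic fractions, paired short reads, long reads, and the
# emulated assembler contig graph.

suppressPackageStartupMessages(library(clonemut))

outdir <- "results/run"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 25, snp_density_per_kb = 10,
                  coverage_short = 60, coverage_long = 15, seed = 20260926)

loci <- simulate_loci(cfg)
truth <- simulate_mutations(loci, cfg)
reads <- simulate_reads(loci, truth, cfg)
graph <- simulate_assembly(loci)

write_fastq(setNames(reads$short$seq1, paste0(reads$short$read_id, "/1")),
            file.path(outdir, "reads_R1.fastq"))
write_fastq(setNames(reads$short$seq2, paste0(reads$short$read_id, "/2")),
            file.path(outdir, "reads_R2.fastq"))
write_fastq(setNames(reads$long$seq, reads$long$read_id),
            file.path(outdir, "reads_long.fastq"))
clonemut:::write_tsv(truth$variants, file.path(outdir, "truth_variants.tsv"))
clonemut:::write_tsv(reads$origins, file.path(outdir, "read_origins.tsv"))
write_contig_graph(graph, file.path(outdir, "assembly"))

cat(sprintf("simulated %d genes (%d bp), %d mutation sites (%.1f sites/kb planted)\n",
            length(loci), sum(truth$gene_lengths),
            length(unique(truth$variants$site_id)),
            1000 * length(unique(truth$variants$site_id)) /
              sum(truth$gene_lengths)))
cat(sprintf("reads: %d pairs (2 x %d bp), %d long reads\n",
            nrow(reads$short), cfg$read_length, nrow(reads$long)))
cat("outputs under", outdir, "\n")
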
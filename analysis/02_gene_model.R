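#!/usr/bin/env Rscript
# Stage 2: build the Reference Gene Model -- one intron-less virtual gene
# sequence per isogroup, contigs ordered by the contig graph -- and pick
# representative isotigs (here scored by length, standing in for homology
# scores).

suppressPackageStartupMessages(library(clonemut))

outdir <- "results/run"
graph <- read_contig_graph(file.path(outdir, "assembly"))
scores <- setNames(nchar(graph$isotigs$sequence), graph$isotigs$isotig_id)
models <- build_gene_models(graph, scores)

write_gene_models(models,
                  file.path(outdir, "gene_models.fasta"),
                  file.path(outdir, "gene_models_offsets.bed"),
                  file.path(outdir, "representatives.tsv"))

lens <- vapply(models, function(m) nchar(m$virtual_sequence), integer(1))
cat(sprintf("built %d gene models, total %d bp (mean %.0f bp)\n",
            length(models), sum(lens), mean(lens)))
cat(sprintf("multi-contig genes: %d; genes with orphan contigs: %d\n",
            sum(vapply(models, function(m) length(m$linear_order) > 1,
                       logical(1))),
            sum(vapply(models, function(m) length(m$orphans) > 0,
                       logical(1)))))
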
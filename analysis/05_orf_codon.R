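#!/usr/bin/env Rscript
# Stage 5: predict longest ORFs on representative isotigs, lift PASS
# variants onto them, classify coding effects, and run the pseudo-SNP
# codon-neutrality simulation (uniform control and usage-weighted) plus
# the codon-position bias of the observed SNPs.

suppressPackageStartupMessages(library(clonemut))

outdir <- "results/run"
graph <- read_contig_graph(file.path(outdir, "assembly"))
refs <- read_fasta(file.path(outdir, "gene_models.fasta"))
reps <- clonemut:::read_tsv(file.path(outdir, "representatives.tsv"))
scores <- setNames(nchar(graph$isotigs$sequence), graph$isotigs$isotig_id)
models <- build_gene_models(graph, scores)
reads <- c(read_fastq(file.path(outdir, "reads_R1.fastq")),
           read_fastq(file.path(outdir, "reads_R2.fastq")))
params <- scoring_params()
mapped <- map_reads(reads, refs, params)
pile <- build_pileup(mapped$alignments, reads, refs, params)
calls <- filter_clonal(call_variants(pile))
pass <- calls[calls$filter == "PASS", ]

rep_seqs <- setNames(
  graph$isotigs$sequence[match(reps$representative_isotig_id,
                               graph$isotigs$isotig_id)],
  reps$gene_id)
orfs <- lapply(names(rep_seqs), function(g) predict_longest_orf(rep_seqs[[g]]))
names(orfs) <- names(rep_seqs)
valid <- !vapply(orfs, is.null, logical(1))

effects <- list()
for (g in names(orfs)[valid]) {
  vg <- pass[pass$gene_id == g, , drop = FALSE]
  if (!nrow(vg)) next
  path <- graph$isotigs$path[[match(reps$representative_isotig_id[
    reps$gene_id == g], graph$isotigs$isotig_id)]]
  ex <- clonemut:::expand_call_alleles(vg)
  rp <- model_to_isotig_coords(models[[g]], path, ex$pos)
  ex <- ex[!is.na(rp), , drop = FALSE]; ex$pos <- rp[!is.na(rp)]
  if (!nrow(ex)) next
  e <- annotate_effects(ex, orfs[[g]], rep_seqs[[g]])
  if (nrow(e)) { e$gene_id <- g; effects[[length(effects) + 1]] <- e }
}
effects <- if (length(effects)) do.call(rbind, effects) else
  clonemut:::empty_effects()
clonemut:::write_tsv(effects, file.path(outdir, "effects.tsv"))

orf_nt <- vapply(names(orfs)[valid], function(g)
  clonemut:::orf_cds(orfs[[g]], rep_seqs[[g]]), character(1))
usage <- compute_codon_usage(orf_nt)
clonemut:::write_tsv(usage, file.path(outdir, "codon_usage.tsv"))

ctrl <- neutral_substitution_probability(NULL, mode = "exact")
wtd <- neutral_substitution_probability(setNames(usage$count, usage$codon),
                                        mode = "exact")
bias <- suppressWarnings(codon_position_bias(effects))

cat(sprintf("valid ORFs (>=100 aa): %d of %d genes\n", sum(valid),
            length(orfs)))
if (nrow(effects)) {
  tab <- table(effects$effect)
  cat("effect classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
}
cat(sprintf("neutral amino-acid-substitution probability: %.1f%% (uniform control) vs %.1f%% (usage-weighted)\n",
            100 * ctrl$probability, 100 * wtd$probability))
cat(sprintf("codon-position distribution of in-ORF SNPs: %.2f / %.2f / %.2f\n",
            bias[1], bias[2], bias[3]))
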
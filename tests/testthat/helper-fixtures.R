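# Small hand-built fixtures shared across test files.

# the worked three-contig gene: c1="AAA", c2="CC", c3="GGGG",
# isotigs {c1,c2,c3} and {c1,c3}
three_contig_graph <- function() {
  contig_graph(
    contigs = c(c1 = "AAA", c2 = "CC", c3 = "GGGG"),
    contig_gene = c(c1 = "g1", c2 = "g1", c3 = "g1"),
    edges = data.frame(gene_id = "g1",
                       from = c("c1", "c2", "c1"),
                       to = c("c2", "c3", "c3"),
                       stringsAsFactors = FALSE),
    isotigs = {
      iso <- data.frame(gene_id = c("g1", "g1"),
                        isotig_id = c("t1", "t2"),
                        sequence = c("AAACCGGGG", "AAAGGGG"),
                        stringsAsFactors = FALSE)
      iso$path <- list(c("c1", "c2", "c3"), c("c1", "c3"))
      iso
    }
  )
}

# a locus list with two genes sharing no sequence, each two isoforms
small_sim <- function(seed = 11, n_genes = 3, density = 10,
                      coverage = 60, error = 0, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed,
                    snp_density_per_kb = density,
                    coverage_short = coverage, coverage_long = 10,
                    error_rate = error, long_error_rate = error, ...)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg)
  list(cfg = cfg, loci = loci, truth = truth)
}

# fractions drawn only from the clonal band (all planted alleles pass the
# window filter)
clonal_only_classes <- function() {
  data.frame(class = "clonal", weight = 1, lo = 0.10, hi = 0.28,
             stringsAsFactors = FALSE)
}

# run simulate -> model -> map -> pileup -> call -> filter on one config
run_clonal_pipeline <- function(cfg) {
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg)
  reads <- simulate_reads(loci, truth, cfg, libraries = "short")
  graph <- simulate_assembly(loci)
  models <- build_gene_models(
    graph, setNames(nchar(graph$isotigs$sequence), graph$isotigs$isotig_id))
  refs <- vapply(models, `[[`, character(1), "virtual_sequence")
  rv <- c(setNames(reads$short$seq1, paste0(reads$short$read_id, "/1")),
          setNames(reads$short$seq2, paste0(reads$short$read_id, "/2")))
  mapped <- map_reads(rv, refs)
  pile <- build_pileup(mapped$alignments, rv, refs)
  calls <- filter_clonal(call_variants(pile))
  list(loci = loci, truth = truth, reads = reads, graph = graph,
       models = models, refs = refs, mapped = mapped, pile = pile,
       calls = calls)
}

expect_valid_locus <- function(locus) {
  expect_true(all(nchar(locus$exons) > 0))
  expect_true(all(grepl("^[ACGT]+$", locus$exons)))
  for (p in locus$isoforms$exon_idx) {
    expect_true(all(diff(p) > 0) || length(p) == 1)
    expect_true(all(p >= 1 & p <= length(locus$exons)))
  }
  covered <- sort(unique(unlist(locus$isoforms$exon_idx)))
  expect_identical(covered, seq_along(locus$exons))
}
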
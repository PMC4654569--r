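test_that("simulate_loci satisfies locus invariants and degenerate cases", {
  cfg1 <- sim_config(n_genes = 1, exon_count_range = c(1, 1),
                     n_isoform_range = c(1, 1), seed = 3)
  loci <- simulate_loci(cfg1)
  expect_length(loci, 1)
  expect_identical(isoform_sequence(loci[[1]], 1), loci[[1]]$exons[1])

  cfg <- sim_config(n_genes = 8, seed = 5)
  for (locus in simulate_loci(cfg)) expect_valid_locus(locus)
})

test_that("the same seed reproduces the full dataset bit-identically", {
  cfg <- sim_config(n_genes = 4, seed = 99, coverage_short = 20,
                    coverage_long = 5)
  run <- function() {
    loci <- simulate_loci(cfg)
    truth <- simulate_mutations(loci, cfg)
    reads <- simulate_reads(loci, truth, cfg)
    list(loci, truth, reads)
  }
  expect_identical(run(), run())
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(snp_density_per_kb = -1),
               class = "clonemut_config_error")
  expect_error(sim_config(exon_count_range = c(5, 2)),
               class = "clonemut_config_error")
  expect_error(sim_config(fraction_classes = data.frame(
    class = "x", weight = 1, lo = 0, hi = 0.4)),
    class = "clonemut_config_error")
  cfg <- sim_config(n_genes = 1, coverage_short = 0)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg)
  expect_error(simulate_reads(loci, truth, cfg, libraries = "short"),
               class = "clonemut_config_error")
})

test_that("planted mutation counts match the density * length expectation", {
  # Monte-Carlo mean over replicate seeds vs the analytic Poisson mean
  cfg0 <- sim_config(n_genes = 1, exon_count_range = c(4, 4),
                     exon_length_range = c(500, 500),
                     n_isoform_range = c(1, 1),
                     snp_density_per_kb = 10, seed = 1)
  loci <- simulate_loci(cfg0)
  len <- nchar(locus_sequence(loci[[1]]))
  counts <- vapply(1:300, function(s) {
    cfg <- cfg0; cfg$seed <- s
    length(unique(simulate_mutations(loci, cfg)$variants$site_id))
  }, numeric(1))
  expected <- 10 * len / 1000
  se <- sqrt(expected / 300)  # Poisson sd over replicates
  expect_lt(abs(mean(counts) - expected), 4 * se)

  cfg_zero <- sim_config(n_genes = 2, snp_density_per_kb = 0, seed = 2)
  loci0 <- simulate_loci(cfg_zero)
  expect_identical(nrow(simulate_mutations(loci0, cfg_zero)$variants), 0L)
})

test_that("a forced site can carry five alleles with prescribed fractions", {
  sim <- small_sim(seed = 21, n_genes = 1, density = 0)
  forced <- list(list(gene_id = "g001", pos = 50L,
                      fractions = c(0.30, 0.10, 0.05, 0.05)))
  truth <- simulate_mutations(sim$loci, sim$cfg, forced_sites = forced)
  site <- truth$variants[truth$variants$pos == 50L, ]
  expect_identical(nrow(site), 4L)              # 4 alts + ref = 5 alleles
  expect_setequal(site$fraction, c(0.30, 0.10, 0.05, 0.05))
  expect_identical(sum(site$alt == "-"), 1L)    # the 4th allele is a deletion
  expect_lte(sum(site$fraction), 1)
})

test_that("allelic fractions per site never exceed 1 and positions are in range", {
  sim <- small_sim(seed = 33, n_genes = 6, density = 25)
  v <- sim$truth$variants
  for (sid in unique(v$site_id))
    expect_lte(sum(v$fraction[v$site_id == sid]), 1 + 1e-12)
  lens <- sim$truth$gene_lengths[v$gene_id]
  expect_true(all(v$pos >= 0 & v$pos < lens))
  # planted reference bases match the concatenated exon sequence
  seqs <- vapply(sim$loci, locus_sequence, character(1))
  names(seqs) <- vapply(sim$loci, `[[`, character(1), "gene_id")
  expect_identical(v$ref,
                   unname(substring(seqs[v$gene_id], v$pos + 1, v$pos + 1)))
})

test_that("error-free reads without variants are exact isoform substrings", {
  cfg <- sim_config(n_genes = 2, snp_density_per_kb = 0, error_rate = 0,
                    long_error_rate = 0, coverage_short = 10,
                    coverage_long = 3, seed = 8)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg)
  reads <- simulate_reads(loci, truth, cfg)
  iso_seqs <- unlist(lapply(loci, function(l)
    lapply(seq_len(nrow(l$isoforms)), function(i) isoform_sequence(l, i))))
  both <- c(reads$short$seq1, revcomp_chr(reads$short$seq2),
            reads$long$seq)
  hits <- vapply(both, function(s)
    any(vapply(iso_seqs, function(iso)
      grepl(s, iso, fixed = TRUE) ||
        grepl(revcomp_chr(s), iso, fixed = TRUE), logical(1))),
    logical(1))
  expect_true(all(hits))
})

test_that("reads carry a planted allele at its allelic fraction", {
  # one gene, one site at fraction 0.25, high coverage, no errors
  cfg <- sim_config(n_genes = 1, exon_count_range = c(1, 1),
                    exon_length_range = c(400, 400),
                    n_isoform_range = c(1, 1), snp_density_per_kb = 0,
                    coverage_short = 400, error_rate = 0,
                    fragment_sd = 0, seed = 14)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg, forced_sites = list(
    list(gene_id = "g001", pos = 200L, fractions = 0.25)))
  reads <- simulate_reads(loci, truth, cfg, libraries = "short")
  org <- reads$origins
  alt <- truth$variants$alt[1]
  spans <- org$start <= 200 & org$start + 300 > 200   # fragment covers site
  carried <- grepl(sprintf("200=%s", alt), org$alleles, fixed = TRUE)
  p_hat <- sum(carried) / sum(spans)
  expect_lt(abs(p_hat - 0.25), 4 * sqrt(0.25 * 0.75 / sum(spans)))
})

test_that("paired mates are consistent with the fragment model", {
  cfg <- sim_config(n_genes = 1, exon_count_range = c(1, 1),
                    exon_length_range = c(800, 800),
                    n_isoform_range = c(1, 1), snp_density_per_kb = 0,
                    error_rate = 0, coverage_short = 30,
                    fragment_mean = 300, fragment_sd = 0, seed = 6)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg)
  reads <- simulate_reads(loci, truth, cfg, libraries = "short")
  iso <- isoform_sequence(loci[[1]], 1)
  for (i in seq_len(nrow(reads$short))) {
    org <- reads$origins[reads$origins$read_id == reads$short$read_id[i], ]
    frag <- substr(iso, org$start + 1, org$start + 300)
    if (org$strand == "-") frag <- revcomp_chr(frag)
    expect_identical(reads$short$seq1[i], substr(frag, 1, 200))
    expect_identical(reads$short$seq2[i],
                     revcomp_chr(substr(frag, 101, 300)))
  }
})

test_that("emulated assembly reproduces exon adjacency and isotig walks", {
  g <- simulate_assembly(list(list(
    gene_id = "g1",
    exons = c("AAA", "CC", "GGGG"),
    isoforms = {
      iso <- data.frame(isoform_id = c("g1_i1", "g1_i2"),
                        weight = c(1, 1), stringsAsFactors = FALSE)
      iso$exon_idx <- list(1:3, c(1L, 3L))
      iso
    })))
  expect_setequal(names(g$contigs), c("g1_c01", "g1_c02", "g1_c03"))
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("g1_c01 g1_c02", "g1_c02 g1_c03", "g1_c01 g1_c03"))

  # single-exon gene: one contig, no edges
  g1 <- simulate_assembly(list(list(
    gene_id = "g9", exons = "ACGTACGT",
    isoforms = {
      iso <- data.frame(isoform_id = "g9_i1", weight = 1,
                        stringsAsFactors = FALSE)
      iso$exon_idx <- list(1L)
      iso
    })))
  expect_identical(nrow(g1$edges), 0L)
  expect_length(g1$contigs, 1L)

  # every isotig path of a random gene set is a walk in the emitted graph
  sim <- small_sim(seed = 17, n_genes = 10)
  ga <- simulate_assembly(sim$loci)
  edge_key <- paste(ga$edges$from, ga$edges$to)
  for (i in seq_len(nrow(ga$isotigs))) {
    p <- ga$isotigs$path[[i]]
    if (length(p) > 1)
      expect_true(all(paste(p[-length(p)], p[-1]) %in% edge_key))
  }
})

test_that("planted variant coordinates agree with the emitted contigs", {
  sim <- small_sim(seed = 29, n_genes = 5, density = 15)
  graph <- simulate_assembly(sim$loci)
  # concatenating each gene's contigs in genomic order recovers the
  # concatenated exon sequence the truth positions refer to
  for (locus in sim$loci) {
    gid <- locus$gene_id
    cids <- names(graph$contig_gene)[graph$contig_gene == gid]
    concat <- paste(graph$contigs[sort(cids)], collapse = "")
    expect_identical(concat, locus_sequence(locus))
    v <- sim$truth$variants[sim$truth$variants$gene_id == gid, ]
    if (nrow(v))
      expect_identical(v$ref, substring(concat, v$pos + 1, v$pos + 1))
  }
})
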
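# build a pileup directly from hand-made alignments
manual_pileup <- function(reads, refs, params = scoring_params(min_seed = 4,
                                                              min_score = 8,
                                                              trim_to = NULL)) {
  m <- map_reads(reads, refs, params)
  build_pileup(m$alignments, reads, refs, params)
}

test_that("identical error-free reads give a clean pileup column", {
  ref <- c(g1 = random_seq(60))
  reads <- setNames(rep(substr(ref[[1]], 11, 40), 10), paste0("r", 1:10))
  pile <- manual_pileup(reads, ref)
  col <- pile$columns[pile$columns$pos == 25, ]
  base <- substr(ref[[1]], 26, 26)
  expect_identical(col$depth, 10L)
  expect_identical(col[[base]], 10L)
  expect_identical(sum(col[, setdiff(c("A", "C", "G", "T"), base)]), 0L)
  calls <- call_variants(pile)
  expect_identical(nrow(calls), 0L)
})

test_that("a reference-deletion alignment increments both deleted positions", {
  # read skips 2 bases of the reference; cheap gaps force the spanning
  # deletion alignment
  ref <- c(g1 = paste0("AAATTTT", "CC", "GGGGTTT"))
  read <- c(r1 = "AAATTTTGGGGTTT")
  params <- scoring_params(match = 1, mismatch = 2, gap_open = 1,
                           gap_extend = 0.5, min_seed = 4, min_score = 5,
                           trim_to = NULL)
  m <- map_reads(read, ref, params)
  expect_match(m$alignments$cigar, "2D")
  pile <- build_pileup(m$alignments, read, ref, params)
  del_cols <- pile$columns[pile$columns$del > 0, ]
  expect_identical(del_cols$pos, c(7L, 8L))
  expect_identical(del_cols$del, c(1L, 1L))
})

test_that("planted multi-allele fractions are recovered in the pileup", {
  cfg <- sim_config(n_genes = 1, exon_count_range = c(1, 1),
                    exon_length_range = c(500, 500),
                    n_isoform_range = c(1, 1), snp_density_per_kb = 0,
                    coverage_short = 400, error_rate = 0,
                    max_alleles = 4, seed = 61)
  loci <- simulate_loci(cfg)
  truth <- simulate_mutations(loci, cfg, forced_sites = list(
    list(gene_id = "g001", pos = 250L,
         fractions = c(0.30, 0.10, 0.05, 0.05))))
  reads <- simulate_reads(loci, truth, cfg, libraries = "short")
  refs <- setNames(locus_sequence(loci[[1]]), "g001")
  rv <- c(setNames(reads$short$seq1, paste0(reads$short$read_id, "/1")),
          setNames(reads$short$seq2, paste0(reads$short$read_id, "/2")))
  m <- map_reads(rv, refs)
  pile <- build_pileup(m$alignments, rv, refs)
  col <- pile$columns[pile$columns$pos == 250L, ]
  v <- truth$variants[truth$variants$pos == 250L, ]
  subs <- v[v$alt != "-", ]
  for (i in seq_len(nrow(subs))) {
    f_obs <- col[[subs$alt[i]]] / (col$depth + col$del)
    se <- sqrt(subs$fraction[i] * (1 - subs$fraction[i]) /
                 (col$depth + col$del))
    expect_lt(abs(f_obs - subs$fraction[i]), 4 * se)
  }
  expect_gt(col$del, 0L)
})

test_that("call thresholds and zygosity classification follow the rules", {
  mk_pile <- function(ref, A = 0, C = 0, G = 0, T = 0) {
    cols <- data.frame(gene_id = "g1", pos = 5L, ref = ref,
                       A = A, C = C, G = G, T = T, del = 0L,
                       stringsAsFactors = FALSE)
    cols$depth <- cols$A + cols$C + cols$G + cols$T
    list(columns = cols, insertions = clonemut:::empty_insertions())
  }
  # singleton alternate observation: no call
  expect_identical(nrow(call_variants(mk_pile("G", G = 19, T = 1))), 0L)
  # fraction 0.5: heterozygous
  het <- call_variants(mk_pile("G", G = 10, T = 10))
  expect_identical(het$zygosity, "heterozygous")
  expect_identical(het$max_fraction, 0.5)
  # fraction 1.0: homozygous
  hom <- call_variants(mk_pile("G", T = 20))
  expect_identical(hom$zygosity, "homozygous")
  expect_identical(hom$max_fraction, 1)
})

test_that("the clonal filter keeps only window-resident fractions at depth", {
  mk_call <- function(fraction, depth) {
    data.frame(gene_id = "g1", pos = 1L, ref = "A", class = "SNP",
               alt = "T", alt_count = as.character(round(fraction * depth)),
               alt_fraction = as.character(fraction),
               max_fraction = fraction, depth = as.integer(depth),
               zygosity = "heterozygous", filter = ".",
               stringsAsFactors = FALSE)
  }
  expect_identical(filter_clonal(mk_call(0.50, 30))$filter,
                   "ancestral_or_platform")
  expect_identical(filter_clonal(mk_call(0.97, 30))$filter,
                   "ancestral_or_platform")
  expect_identical(filter_clonal(mk_call(0.20, 3))$filter, "PASS")
  expect_identical(filter_clonal(mk_call(0.20, 2))$filter, "low_depth")
  expect_identical(filter_clonal(mk_call(0.03, 40))$filter, "low_fraction")
  # closed endpoints of the retained windows
  expect_identical(filter_clonal(mk_call(0.06, 10))$filter, "PASS")
  expect_identical(filter_clonal(mk_call(0.30, 10))$filter, "PASS")
  expect_identical(filter_clonal(mk_call(0.94, 100))$filter, "PASS")
  # idempotence
  x <- filter_clonal(rbind(mk_call(0.2, 10), mk_call(0.5, 10),
                           mk_call(0.1, 2)))
  expect_identical(filter_clonal(x), x)
})

test_that("widening a retained window never decreases the PASS count", {
  set.seed(73)
  calls <- do.call(rbind, lapply(1:200, function(i) {
    f <- runif(1)
    d <- sample(2:60, 1)
    data.frame(gene_id = "g1", pos = i, ref = "A", class = "SNP",
               alt = "T", alt_count = as.character(max(1, round(f * d))),
               alt_fraction = as.character(f), max_fraction = f,
               depth = d, zygosity = "heterozygous", filter = ".",
               stringsAsFactors = FALSE)
  }))
  widths <- seq(0.05, 0.40, by = 0.05)
  pass <- vapply(widths, function(w) {
    cfgw <- filter_config(windows = list(c(0.06, 0.06 + w)))
    sum(filter_clonal(calls, cfgw)$filter == "PASS")
  }, numeric(1))
  expect_true(all(diff(pass) >= 0))
})

test_that("snp_density computes per-gene and genome-wide rates", {
  calls <- data.frame(gene_id = rep("g1", 12), pos = 1:12, ref = "A",
                      class = "SNP", alt = "T", alt_count = "3",
                      alt_fraction = "0.2", max_fraction = 0.2, depth = 15L,
                      zygosity = "heterozygous", filter = "PASS",
                      stringsAsFactors = FALSE)
  d <- snp_density(calls, c(g1 = 2000L, g2 = 1000L))
  expect_identical(d$per_gene$snps_per_kb, c(6, 0))
  expect_equal(d$genome_rate, 1000 * 12 / 3000)
  expect_error(snp_density(calls, c(g2 = 1000L)),
               class = "clonemut_input_error")
  d0 <- snp_density(calls[0, ], c(g1 = 500L))
  expect_identical(d0$per_gene$snps_per_kb, 0)
})

test_that("ancestral-only heterozygosity is filtered out as coverage grows", {
  # all planted fractions sit at 0.5: the filter should remove everything
  # once depth makes the observed fractions concentrate around 0.5
  anc <- data.frame(class = "ancestral", weight = 1, lo = 0.49, hi = 0.51,
                    stringsAsFactors = FALSE)
  for (cov in c(60, 240)) {
    cfg <- sim_config(n_genes = 2, exon_count_range = c(1, 2),
                      exon_length_range = c(300, 400),
                      n_isoform_range = c(1, 1), snp_density_per_kb = 10,
                      fraction_classes = anc, alt_count_probs = c(1, 0, 0),
                      coverage_short = cov, error_rate = 0, seed = 67)
    loci <- simulate_loci(cfg)
    truth <- simulate_mutations(loci, cfg)
    reads <- simulate_reads(loci, truth, cfg, libraries = "short")
    refs <- vapply(loci, locus_sequence, character(1))
    names(refs) <- vapply(loci, `[[`, character(1), "gene_id")
    rv <- c(setNames(reads$short$seq1, paste0(reads$short$read_id, "/1")),
            setNames(reads$short$seq2, paste0(reads$short$read_id, "/2")))
    m <- map_reads(rv, refs)
    pile <- build_pileup(m$alignments, rv, refs)
    calls <- filter_clonal(call_variants(pile))
    pass_rate <- if (nrow(calls)) mean(calls$filter == "PASS") else 0
    if (cov == 60) pass60 <- pass_rate else pass240 <- pass_rate
  }
  expect_lte(pass240, pass60 + 0.02)
  expect_lt(pass240, 0.1)
})

test_that("written VCF is valid for VariantAnnotation and preserves calls", {
  skip_if_not_installed("VariantAnnotation")
  refs <- c(g1 = paste0(strrep("A", 10), "G", strrep("T", 10)))
  calls <- data.frame(
    gene_id = "g1", pos = c(10L, 10L, 4L), ref = c("G", "G", "A"),
    class = c("SNP", "deletion", "insertion"),
    alt = c("C,T", "-", "+GGA"),
    alt_count = c("5,3", "4", "2"),
    alt_fraction = c("0.25,0.15", "0.2", "0.1"),
    max_fraction = c(0.25, 0.2, 0.1), depth = c(20L, 20L, 20L),
    zygosity = "heterozygous", filter = c("PASS", "PASS", "low_depth"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(calls, refs, path)
  vcf <- VariantAnnotation::readVcf(path)
  expect_identical(length(vcf), 3L)
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_setequal(as.character(GenomicRanges::seqnames(rr)), "g1")
  expect_identical(VariantAnnotation::info(vcf)$DP, rep(20L, 3L))
  snp <- which(lengths(VariantAnnotation::fixed(vcf)$ALT) == 2L)
  expect_identical(as.integer(GenomicRanges::start(rr))[snp], 11L)
})

test_that("written SAM round-trips through Rsamtools", {
  skip_if_not_installed("Rsamtools")
  sim <- small_sim(seed = 77, n_genes = 2, density = 5, coverage = 8,
                   error = 0)
  reads <- simulate_reads(sim$loci, sim$truth, sim$cfg, libraries = "short")
  refs <- vapply(sim$loci, locus_sequence, character(1))
  names(refs) <- vapply(sim$loci, `[[`, character(1), "gene_id")
  rv <- setNames(reads$short$seq1, reads$short$read_id)
  m <- map_reads(rv, refs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(m$alignments, rv, refs, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  expect_identical(length(rec$qname), nrow(m$alignments))
  expect_setequal(as.character(rec$rname), unique(m$alignments$gene_id))
  ord <- match(m$alignments$read_id, rec$qname)
  expect_identical(as.integer(rec$pos[ord]), m$alignments$start + 1L)
})
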
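NONSTOP <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], "ATG")

test_that("the 100-aa boundary is inclusive and ATG is required", {
  set.seed(81)
  body <- paste(sample(NONSTOP, 99, TRUE), collapse = "")
  seq100 <- paste0("ATG", body, "TAA")
  orf <- predict_longest_orf(seq100, min_aa = 100)
  expect_identical(orf$aa_length, 100L)
  expect_identical(substr(orf$aa, 1, 1), "M")
  expect_null(predict_longest_orf(seq100, min_aa = 101))
  # alphabet {A,C} admits no ATG (and no stop) in any frame or strand
  no_atg <- paste(sample(c("A", "C"), 600, TRUE), collapse = "")
  expect_null(predict_longest_orf(no_atg, min_aa = 10))
  expect_false(is.null(predict_longest_orf(no_atg, min_aa = 10,
                                           require_atg = FALSE)))
})

test_that("ORF prediction matches the brute-force six-frame scanner", {
  set.seed(83)
  for (i in 1:120) {
    s <- random_seq(sample(300:1200, 1))
    got <- predict_longest_orf(s, min_aa = 25)
    want <- orf_bruteforce(s, min_aa = 25)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$aa_length, as.integer(want$aa_length))
      expect_identical(got$aa, want$aa)
      # interval bookkeeping: the reported interval translates to the
      # reported protein
      cds <- substr(s, got$start + 1, got$end)
      if (got$strand == "-") cds <- revcomp_chr(cds)
      expect_identical(
        as.character(suppressWarnings(
          Biostrings::translate(Biostrings::DNAString(cds)))), got$aa)
    }
  }
})

test_that("codon usage tallies codons and recovers sampling frequencies", {
  u <- compute_codon_usage("ATGAAATAA")
  expect_identical(u$count[u$codon == "ATG"], 1L)
  expect_identical(u$count[u$codon == "AAA"], 1L)
  expect_identical(u$count[u$codon == "TAA"], 1L)
  expect_identical(sum(u$count), 3L)
  expect_warning(u0 <- compute_codon_usage(character(0)), "no codons")
  expect_true(all(is.na(u0$frequency)))

  # recovery of a known codon distribution within multinomial error
  set.seed(85)
  codons <- c("GCT", "GCC", "AAA", "TGG")
  probs <- c(0.4, 0.3, 0.2, 0.1)
  draw <- sample(codons, 1e5, TRUE, probs)
  u2 <- compute_codon_usage(paste(draw, collapse = ""))
  for (i in seq_along(codons)) {
    se <- sqrt(probs[i] * (1 - probs[i]) / 1e5)
    expect_lt(abs(u2$frequency[u2$codon == codons[i]] - probs[i]), 4 * se)
  }
})

test_that("SNP effect classification follows the genetic code", {
  orf <- list(frame = 1L, strand = "+", start = 0L, end = 9L,
              aa = "MAK", aa_length = 3L)
  seqs <- "ATGGCTAAA"
  eff <- function(pos, ref, alt)
    annotate_effects(data.frame(pos = pos, ref = ref, alt = alt,
                                class = "SNP", stringsAsFactors = FALSE),
                     orf, seqs)
  # GCT -> GCC, codon position 3: synonymous (Ala -> Ala)
  e <- eff(5L, "T", "C")
  expect_identical(e$effect, "synonymous coding")
  expect_identical(e$codon_pos, 3L)
  # AAA -> GAA, position 1: non-synonymous (Lys -> Glu)
  e <- eff(6L, "A", "G")
  expect_identical(e$effect, "non-synonymous coding")
  expect_identical(c(e$aa_ref, e$aa_alt), c("K", "E"))
  # TGG with G->A at codon position 2 gives TAG... use a TGG codon
  orf2 <- list(frame = 1L, strand = "+", start = 0L, end = 9L,
               aa = "MWK", aa_length = 3L)
  e <- annotate_effects(data.frame(pos = 4L, ref = "G", alt = "A",
                                   class = "SNP", stringsAsFactors = FALSE),
                        orf2, "ATGTGGAAA")
  expect_identical(e$effect, "stop gained")
  # out-of-ORF variants yield no record
  expect_identical(nrow(eff(8L, "A", "T")), 1L)
  e <- annotate_effects(data.frame(pos = 9L, ref = "A", alt = "T",
                                   class = "SNP", stringsAsFactors = FALSE),
                        orf, "ATGGCTAAAA")
  expect_identical(nrow(e), 0L)
  # inconsistent reference allele is an input error
  expect_error(eff(5L, "G", "C"), class = "clonemut_input_error")
})

test_that("InDel effects distinguish frame shifts from codon-level edits", {
  # ORF: ATG GCT GAT AAA -> M A D K
  s <- "ATGGCTGATAAA"
  orf <- list(frame = 1L, strand = "+", start = 0L, end = 12L,
              aa = "MADK", aa_length = 4L)
  ind <- function(pos, class, alt = "-", len = 1L)
    annotate_effects(data.frame(pos = pos, ref = substr(s, pos + 1, pos + 1),
                                alt = alt, class = class, indel_len = len,
                                stringsAsFactors = FALSE), orf, s)
  expect_identical(ind(3L, "deletion", "-", 1L)$effect, "frame shift")
  # deleting one whole codon (positions 3-5, codon-aligned)
  expect_identical(ind(3L, "deletion", "-", 3L)$effect, "codon deletion")
  # 3-base deletion straddling codons
  expect_identical(ind(4L, "deletion", "-", 3L)$effect,
                   "codon change plus codon deletion")
  # codon-aligned 3-base insertion (after position 2, at a codon boundary)
  expect_identical(ind(2L, "insertion", "+AAA")$effect, "codon insertion")
  expect_identical(ind(3L, "insertion", "+AAA")$effect,
                   "codon change plus codon insertion")
  expect_identical(ind(2L, "insertion", "+AA")$effect, "frame shift")
  # an in-frame insertion that introduces a stop codon
  expect_identical(ind(2L, "insertion", "+TAA")$effect, "stop gained")
})

test_that("per-codon substitution classes sum to 9 and match effect annotation", {
  classes <- clonemut:::codon_substitution_classes()
  expect_identical(nrow(classes), 61L)
  expect_true(all(classes$n_synonymous + classes$n_nonsynonymous +
                    classes$n_stop_gained == 9L))
  # consistency with annotate_effects applied to every substitution of a
  # sample of codons embedded in a minimal ORF
  set.seed(87)
  for (cd in sample(classes$codon, 8)) {
    s <- paste0("ATG", cd, "GAA")
    orf <- list(frame = 1L, strand = "+", start = 0L, end = 9L,
                aa = as.character(suppressWarnings(Biostrings::translate(
                  Biostrings::DNAString(s)))), aa_length = 3L)
    tallies <- c(`synonymous coding` = 0, `non-synonymous coding` = 0,
                 `stop gained` = 0)
    for (p in 0:2) {
      ref <- substr(cd, p + 1, p + 1)
      for (b in setdiff(c("A", "C", "G", "T"), ref)) {
        e <- annotate_effects(data.frame(pos = 3L + p, ref = ref, alt = b,
                                         class = "SNP",
                                         stringsAsFactors = FALSE), orf, s)
        tallies[e$effect] <- tallies[e$effect] + 1
      }
    }
    row <- classes[classes$codon == cd, ]
    expect_identical(unname(tallies),
                     as.numeric(c(row$n_synonymous, row$n_nonsynonymous,
                                  row$n_stop_gained)))
  }
})

test_that("neutral substitution probability: certainties and enumeration", {
  # all weight on TGG (Trp): every substitution changes the amino acid
  expect_identical(
    neutral_substitution_probability(c(TGG = 1))$probability, 1)
  # uniform sense-codon enumeration equals the independent oracle
  exact <- neutral_substitution_probability()
  expect_equal(exact$probability, codon_change_oracle())
  expect_equal(exact$probability, 415 / 549)
  # excluding stop-gains lowers the probability
  no_stop <- neutral_substitution_probability(include_stop_gain = FALSE)
  expect_equal(no_stop$probability, codon_change_oracle(FALSE))
  expect_lt(no_stop$probability, exact$probability)
  expect_error(neutral_substitution_probability(c(TAA = 1)),
               class = "clonemut_input_error")
})

test_that("Monte-Carlo mode converges to exact mode for arbitrary weights", {
  set.seed(89)
  w <- setNames(runif(61), clonemut:::codon_substitution_classes()$codon)
  exact <- neutral_substitution_probability(w)$probability
  mc <- neutral_substitution_probability(w, mode = "simulate", n = 2e5,
                                         seed = 5)
  expect_lt(abs(mc$probability - exact), 3 * mc$se + 1e-9)
})

test_that("codon position bias is recovered from planted weights", {
  expect_warning(b0 <- codon_position_bias(clonemut:::empty_effects()),
                 "undefined")
  expect_true(all(is.na(b0)))
  # a locus that is one long ORF, so the planting pool spans ~3000 bp and
  # weighted sampling without replacement barely depletes any position class
  set.seed(91)
  exon <- paste0("ATG", paste(sample(NONSTOP, 990, TRUE), collapse = ""),
                 "TAA")
  iso <- data.frame(isoform_id = "gORF_i1", weight = 1,
                    stringsAsFactors = FALSE)
  iso$exon_idx <- list(1L)
  locus <- list(gene_id = "gORF", exons = exon, isoforms = iso)
  for (w in list(c(1, 1, 1) / 3, c(0.2, 0.2, 0.6))) {
    cfg <- sim_config(n_genes = 1, snp_density_per_kb = 15,
                      codon_position_weights = w, seed = 91)
    truth <- simulate_mutations(list(locus), cfg)
    v <- truth$variants[!is.na(truth$variants$codon_pos), ]
    n <- nrow(v)
    obs <- as.numeric(table(factor(v$codon_pos, levels = 1:3))) / n
    for (k in 1:3)
      expect_lt(abs(obs[k] - w[k]), 4 * sqrt(w[k] * (1 - w[k]) / n) + 0.03)
  }
})
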
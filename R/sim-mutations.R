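#' Plant clonal mutations on simulated loci
#'
#' Mutation sites are placed along each locus's concatenated exon sequence at
#' an expected density of `config$snp_density_per_kb` per 1000 bp (Poisson
#' count, distinct positions). Each site carries 1 or more alternate alleles;
#' per-alt allelic fractions are drawn from the configured mixture and, when
#' their sum exceeds 1, are normalized so the reference allele retains the
#' remainder. The first three alternate alleles at a site are distinct
#' non-reference bases; a fourth is a single-base deletion.
#'
#' When `config$codon_position_weights` is set, sites are restricted to the
#' longest forward-strand ORF of the concatenated sequence and codon positions
#' 1/2/3 are sampled with the given weights (falling back to uniform placement
#' for loci without an ORF of at least 30 codons).
#'
#' @param loci result of [simulate_loci()].
#' @param config a [sim_config()].
#' @param forced_sites optional list of sites to plant verbatim before random
#'   placement; each element a list with `gene_id`, `pos` (0-based on the
#'   concatenated exon sequence) and `fractions` (one per alternate allele,
#'   in decreasing order of how many substitution alleles are available).
#' @return a truth object (class `clonemut_sim_truth`): list with `variants`
#'   (data frame: gene_id, site_id, pos, ref, alt, fraction, class,
#'   codon_pos), `gene_lengths` (named integer), `snp_density_per_kb`, and
#'   `codon_position_weights`.
#' @export
simulate_mutations <- function(loci, config, forced_sites = NULL) {
  validate_sim_config(config)
  if (config$snp_density_per_kb < 0) config_error("snp_density_per_kb must be >= 0")
  gene_seqs <- vapply(loci, locus_sequence, character(1))
  names(gene_seqs) <- vapply(loci, `[[`, character(1), "gene_id")

  withr::with_seed(config$seed + 202L, {
    rows <- list()
    for (locus in loci) {
      gid <- locus$gene_id
      seq <- gene_seqs[[gid]]
      len <- nchar(seq)
      forced <- Filter(function(f) identical(f$gene_id, gid), forced_sites %||% list())
      taken <- integer(0)
      for (f in forced) {
        rows[[length(rows) + 1L]] <-
          make_site(gid, f$pos, seq, length(f$fractions), f$fractions, NA_integer_)
        taken <- c(taken, f$pos)
      }
      n_var <- rpois(1L, config$snp_density_per_kb * len / 1000)
      n_var <- min(n_var, len - length(taken))
      if (n_var <= 0L) next
      pos_pool <- setdiff(seq_len(len) - 1L, taken)
      cpw <- config$codon_position_weights
      codon_pos <- rep(NA_integer_, n_var)
      if (!is.null(cpw)) {
        orf <- predict_longest_orf(seq, min_aa = 30L, frames = "forward")
        if (!is.null(orf)) {
          in_orf <- pos_pool[pos_pool >= orf$start & pos_pool < orf$end]
          cp <- ((in_orf - orf$start) %% 3L) + 1L
          w <- cpw[cp]
          n_var <- min(n_var, length(in_orf))
          pick <- sample(seq_along(in_orf), n_var, prob = w)
          pos <- in_orf[pick]
          codon_pos <- cp[pick]
        } else {
          pos <- sample(pos_pool, n_var)
        }
      } else {
        pos <- sample(pos_pool, n_var)
      }
      n_alt_probs <- rep_len(config$alt_count_probs, config$max_alleles)
      n_alts <- sample.int(config$max_alleles, n_var, replace = TRUE,
                           prob = n_alt_probs)
      for (i in seq_len(n_var)) {
        rows[[length(rows) + 1L]] <-
          make_site(gid, pos[i], seq, n_alts[i], NULL, codon_pos[i],
                    config$fraction_classes)
      }
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(0), site_id = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 fraction = numeric(0), class = character(0),
                 codon_pos = integer(0), stringsAsFactors = FALSE)
    variants <- variants[order(variants$gene_id, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    structure(list(
      variants = variants,
      gene_lengths = setNames(nchar(gene_seqs), names(gene_seqs)),
      snp_density_per_kb = config$snp_density_per_kb,
      codon_position_weights = config$codon_position_weights
    ), class = "clonemut_sim_truth")
  })
}

# build the per-alt rows for one mutation site
make_site <- function(gid, pos, seq, n_alt, fractions, codon_pos,
                      fraction_classes = NULL) {
  ref <- substr(seq, pos + 1L, pos + 1L)
  subs <- setdiff(DNA_BASES, ref)
  n_sub <- min(n_alt, 3L)
  alts <- sample(subs, n_sub)
  if (n_alt > 3L) alts <- c(alts, "-")
  if (is.null(fractions)) {
    fc <- fraction_classes
    ci <- sample.int(nrow(fc), n_alt, replace = TRUE, prob = fc$weight)
    fractions <- runif(n_alt, fc$lo[ci], fc$hi[ci])
    cls <- fc$class[ci]
  } else {
    if (length(fractions) != n_alt)
      config_error("forced site fractions must match its allele count")
    cls <- rep("forced", n_alt)
  }
  if (sum(fractions) > 1) fractions <- fractions / sum(fractions)
  data.frame(
    gene_id = gid,
    site_id = sprintf("%s:%d", gid, pos),
    pos = as.integer(pos),
    ref = ref,
    alt = alts,
    fraction = fractions,
    class = cls,
    codon_pos = codon_pos,
    stringsAsFactors = FALSE
  )
}
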
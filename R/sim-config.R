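#' Configuration for the clonal transcriptome simulator
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' Defaults emulate a clonal planarian transcriptome: multi-exon loci whose isoforms share
#' exons, a clonal population carrying heterozygous-like mutations at several
#' allelic fractions per site (including sites with more than two alleles),
#' paired short reads (2 x 200 bp after emulated 5' trimming) and single-end
#' long reads (300-700 bp), with platform-like substitution error rates.
#'
#' @param n_genes number of simulated gene loci.
#' @param exon_count_range integer range (min, max); exon number per locus is
#'   drawn uniformly from it.
#' @param exon_length_range integer range (min, max) of exon lengths in bp.
#' @param n_isoform_range integer range (min, max) of isoforms per locus; the
#'   first isoform always contains every exon so the locus is fully expressed.
#' @param snp_density_per_kb expected planted mutations per 1000 bp of
#'   concatenated exon sequence. Default 10, the scale of mutation load
#'   measured in clonal planarian strains (about 9 PASS SNPs/kb).
#' @param fraction_classes data frame describing the mixture the per-alt
#'   allelic fractions are drawn from, with columns `class`, `weight`, `lo`,
#'   `hi` (fractions uniform on \[lo, hi\]). The default mixture puts 70% of
#'   alts in the clonal band (0.06-0.30), 20% at ancestral-heterozygosity-like
#'   0.5, and 10% near 1.0 (platform-bias-like), mirroring the three
#'   populations the allelic-fraction filter is designed to separate.
#' @param alt_count_probs probabilities that a mutated site carries 1, 2, ...
#'   alternate alleles (recycled up to `max_alleles`); multi-alt sites emulate
#'   the >2-allele sites seen in the clonal strain.
#' @param max_alleles maximum number of alternate alleles per site (<= 4).
#'   Substitution alleles are distinct non-reference bases, so at most 3; a
#'   fourth alternate allele, when drawn, is a single-base deletion, which is
#'   how a site can carry five alleles (reference + 4) as observed in
#'   SNP-rich regions of the clonal strain.
#' @param codon_position_weights optional length-3 non-negative weights
#'   summing to 1; when supplied, planted mutations are restricted to the
#'   longest ORF of the locus and placed at codon positions 1/2/3 with these
#'   weights (used to emulate third-position bias).
#' @param coverage_short,coverage_long mean fold-coverage of the short-read
#'   pairs and long reads over the concatenated exon sequence.
#' @param read_length short-read length (each mate), bp.
#' @param long_read_range length range of the single-end long reads, bp.
#' @param fragment_mean,fragment_sd normal fragment-size model for pairs, bp.
#' @param error_rate,long_error_rate per-base substitution error rates.
#' @param indel_error_rate per-base indel error rate (default 0; substitution
#'   -only error keeps truth evaluation exact).
#' @param seed integer seed fixing all randomness end-to-end.
#'
#' @return a validated list of class `clonemut_sim_config`.
#' @export
sim_config <- function(n_genes = 30,
                       exon_count_range = c(2L, 6L),
                       exon_length_range = c(150L, 500L),
                       n_isoform_range = c(1L, 3L),
                       snp_density_per_kb = 10,
                       fraction_classes = default_fraction_classes(),
                       alt_count_probs = c(0.85, 0.10, 0.05),
                       max_alleles = 3L,
                       codon_position_weights = NULL,
                       coverage_short = 100,
                       coverage_long = 20,
                       read_length = 200L,
                       long_read_range = c(300L, 700L),
                       fragment_mean = 300,
                       fragment_sd = 30,
                       error_rate = 0.005,
                       long_error_rate = 0.01,
                       indel_error_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_length_range = as.integer(exon_length_range),
    n_isoform_range = as.integer(n_isoform_range),
    snp_density_per_kb = snp_density_per_kb,
    fraction_classes = fraction_classes,
    alt_count_probs = alt_count_probs,
    max_alleles = as.integer(max_alleles),
    codon_position_weights = codon_position_weights,
    coverage_short = coverage_short,
    coverage_long = coverage_long,
    read_length = as.integer(read_length),
    long_read_range = as.integer(long_read_range),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    error_rate = error_rate,
    long_error_rate = long_error_rate,
    indel_error_rate = indel_error_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "clonemut_sim_config"
  cfg
}

#' Default allelic-fraction mixture of the simulator
#'
#' Three components: the clonal band (somatic mutations at low cellular
#' fraction), ancestral heterozygosity near 0.5, and platform-bias-like
#' fractions near 1.0.
#' @return data frame with columns class, weight, lo, hi.
#' @export
default_fraction_classes <- function() {
  data.frame(
    class  = c("clonal", "ancestral", "platform"),
    weight = c(0.70, 0.20, 0.10),
    lo     = c(0.06, 0.48, 0.95),
    hi     = c(0.30, 0.52, 0.99),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, nm, min_ok = 1L) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < min_ok)
      config_error(sprintf("invalid %s: must be (min, max) with min <= max and min >= %d", nm, min_ok))
  }
  if (is.na(cfg$n_genes) || cfg$n_genes < 0L)
    config_error("n_genes must be a non-negative integer")
  chk_range(cfg$exon_count_range, "exon_count_range")
  chk_range(cfg$exon_length_range, "exon_length_range")
  chk_range(cfg$n_isoform_range, "n_isoform_range")
  chk_range(cfg$long_read_range, "long_read_range")
  if (is.na(cfg$snp_density_per_kb) || cfg$snp_density_per_kb < 0)
    config_error("snp_density_per_kb must be >= 0")
  fc <- cfg$fraction_classes
  if (!is.data.frame(fc) || !all(c("class", "weight", "lo", "hi") %in% names(fc)) ||
      nrow(fc) == 0L || any(fc$weight < 0) || sum(fc$weight) <= 0 ||
      any(fc$lo <= 0) || any(fc$hi > 1) || any(fc$lo > fc$hi))
    config_error("fraction_classes must have columns class/weight/lo/hi with 0 < lo <= hi <= 1 and non-negative weights")
  if (any(cfg$alt_count_probs < 0) || sum(cfg$alt_count_probs) <= 0)
    config_error("alt_count_probs must be non-negative with positive sum")
  if (cfg$max_alleles < 1L || cfg$max_alleles > 4L)
    config_error("max_alleles must be in 1..4 (3 distinct substitution alleles; a 4th alt is a 1-bp deletion)")
  if (!is.null(cfg$codon_position_weights)) {
    w <- cfg$codon_position_weights
    if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      config_error("codon_position_weights must be 3 non-negative values summing to 1")
  }
  for (nm in c("coverage_short", "coverage_long", "error_rate",
               "long_error_rate", "indel_error_rate", "fragment_sd"))
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      config_error(sprintf("%s must be >= 0", nm))
  if (cfg$read_length < 20L) config_error("read_length must be >= 20")
  if (cfg$fragment_mean < cfg$read_length)
    config_error("fragment_mean must be >= read_length")
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
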
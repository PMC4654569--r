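#' Read a pipeline configuration from YAML
#'
#' The file may contain sections `sim` (arguments of [sim_config()]),
#' `filter` ([filter_config()]), `scoring` ([scoring_params()]), `kmer`
#' (`k`), `annotation` ([simulate_annotation()] arguments) and `de`
#' ([differential_expression()] thresholds). Missing sections fall back to
#' package defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's `sim$seed`.
#' @return pipeline configuration list.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  pipeline_config(sim = y$sim %||% list(), filter = y$filter %||% list(),
                  scoring = y$scoring %||% list(),
                  kmer_k = y$kmer$k %||% 21L,
                  annotation = y$annotation %||% list(),
                  de = y$de %||% list(), seed = seed)
}

#' Assemble a pipeline configuration from argument lists
#'
#' @param sim,filter,scoring,annotation,de argument lists for the
#'   respective constructors/functions.
#' @param kmer_k k-mer size for the spectrum stage.
#' @param seed optional global seed override.
#' @return pipeline configuration list (class `clonemut_pipeline_config`).
#' @export
pipeline_config <- function(sim = list(), filter = list(), scoring = list(),
                            kmer_k = 21L, annotation = list(), de = list(),
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(
    sim = do.call(sim_config, sim),
    filter = do.call(filter_config, filter),
    scoring = do.call(scoring_params, scoring),
    kmer_k = as.integer(kmer_k),
    annotation = annotation,
    de = de
  ), class = "clonemut_pipeline_config")
}

#' Run the full clonal-mutation analysis pipeline on simulated data
#'
#' Executes the stages in dependency order -- simulate reads and assembly,
#' build Reference Gene Models, map and count reads, pile up and call
#' variants, apply the clonal filter and compute SNP densities, predict
#' ORFs and classify coding effects, run the codon-neutrality simulation,
#' compute the k-mer spectrum of the reads, and produce category-bias and
#' (null split) differential-expression tables -- writing every intermediate
#' as a plain-text file under `outdir` and returning a manifest of outputs
#' and per-stage summary counts. Identical configuration and seed give an
#' identical manifest.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param outdir output directory.
#' @param seed optional seed override.
#' @return the run manifest (list; also written to `manifest.json`).
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config, seed)
  else if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  paths <- list(); summary <- list()

  # --- simulate -------------------------------------------------------------
  loci <- simulate_loci(config$sim)
  truth <- simulate_mutations(loci, config$sim)
  reads <- simulate_reads(loci, truth, config$sim)
  graph <- simulate_assembly(loci)
  paths$reads_r1 <- file.path(outdir, "reads_R1.fastq")
  paths$reads_r2 <- file.path(outdir, "reads_R2.fastq")
  paths$reads_long <- file.path(outdir, "reads_long.fastq")
  write_fastq(setNames(reads$short$seq1,
                       paste0(reads$short$read_id, "/1")), paths$reads_r1)
  write_fastq(setNames(reads$short$seq2,
                       paste0(reads$short$read_id, "/2")), paths$reads_r2)
  write_fastq(setNames(reads$long$seq, reads$long$read_id), paths$reads_long)
  paths$truth <- file.path(outdir, "truth_variants.tsv")
  write_tsv(truth$variants, paths$truth)
  paths$origins <- file.path(outdir, "read_origins.tsv")
  write_tsv(reads$origins, paths$origins)
  paths$assembly <- file.path(outdir, "assembly")
  write_contig_graph(graph, paths$assembly)
  summary$n_genes <- length(loci)
  summary$n_planted_sites <- length(unique(truth$variants$site_id))
  summary$n_read_pairs <- nrow(reads$short)
  summary$n_long_reads <- nrow(reads$long)
  stage_log("simulate", "%d genes, %d mutation sites, %d read pairs",
            summary$n_genes, summary$n_planted_sites, summary$n_read_pairs)

  # --- gene models ----------------------------------------------------------
  scores <- setNames(nchar(graph$isotigs$sequence), graph$isotigs$isotig_id)
  models <- build_gene_models(graph, scores)
  refs <- vapply(models, `[[`, character(1), "virtual_sequence")
  paths$model_fasta <- file.path(outdir, "gene_models.fasta")
  paths$model_bed <- file.path(outdir, "gene_models_offsets.bed")
  paths$representatives <- file.path(outdir, "representatives.tsv")
  write_gene_models(models, paths$model_fasta, paths$model_bed,
                    paths$representatives)
  summary$n_models <- length(models)
  stage_log("build-model", "%d gene models, total %d bp",
            length(models), sum(nchar(refs)))

  # --- map + count ----------------------------------------------------------
  read_vec <- c(setNames(reads$short$seq1, paste0(reads$short$read_id, "/1")),
                setNames(reads$short$seq2, paste0(reads$short$read_id, "/2")))
  mapped <- map_reads(read_vec, refs, config$scoring)
  trimmed <- if (!is.null(config$scoring$trim_to))
    ifelse(nchar(read_vec) > config$scoring$trim_to,
           substr(read_vec, 1L, config$scoring$trim_to), read_vec)
  else read_vec
  paths$sam <- file.path(outdir, "alignments.sam")
  write_sam(mapped$alignments, trimmed, refs, paths$sam)
  counts <- count_reads(mapped$alignments, gene_ids = names(refs))
  paths$counts <- file.path(outdir, "counts.tsv")
  write_tsv(counts, paths$counts)
  summary$n_reads <- length(read_vec)
  summary$n_mapped <- nrow(mapped$alignments)
  summary$mapping_rate <- mapped$mapping_rate
  summary$n_ambiguous <- sum(mapped$alignments$ambiguous)
  stage_log("map", "mapping rate %.1f%% (%d/%d reads, %d ambiguous)",
            100 * mapped$mapping_rate, summary$n_mapped, summary$n_reads,
            summary$n_ambiguous)

  # --- variants -------------------------------------------------------------
  pile <- build_pileup(mapped$alignments, trimmed, refs,
                       config$scoring, trim = FALSE)
  calls <- call_variants(pile, config$filter)
  calls <- filter_clonal(calls, config$filter)
  paths$vcf <- file.path(outdir, "variants.vcf")
  write_variant_vcf(calls, refs, paths$vcf)
  dens <- snp_density(calls, setNames(nchar(refs), names(refs)))
  paths$density <- file.path(outdir, "snp_density.tsv")
  write_tsv(dens$per_gene, paths$density)
  paths$density_hist <- file.path(outdir, "snp_density_hist.tsv")
  write_tsv(dens$histogram, paths$density_hist)
  summary$n_calls <- nrow(calls)
  summary$n_pass <- sum(calls$filter == "PASS")
  summary$genome_snps_per_kb <- dens$genome_rate
  stage_log("call", "%d calls, %d PASS, %.2f SNPs/kb genome-wide",
            summary$n_calls, summary$n_pass, dens$genome_rate)

  # --- ORFs, effects, codon statistics -------------------------------------
  rep_seqs <- setNames(
    graph$isotigs$sequence[match(
      vapply(models, `[[`, character(1), "representative_isotig_id"),
      graph$isotigs$isotig_id)],
    names(models))
  orfs <- lapply(names(models), function(g)
    predict_longest_orf(rep_seqs[[g]]))
  names(orfs) <- names(models)
  valid <- !vapply(orfs, is.null, logical(1))
  eff_all <- list(); n_nonrep <- 0L
  pass_snps <- calls[calls$filter == "PASS", , drop = FALSE]
  for (g in names(models)[valid]) {
    vg <- pass_snps[pass_snps$gene_id == g, , drop = FALSE]
    if (!nrow(vg)) next
    path_g <- graph$isotigs$path[[
      match(models[[g]]$representative_isotig_id, graph$isotigs$isotig_id)]]
    expanded <- expand_call_alleles(vg)
    rep_pos <- model_to_isotig_coords(models[[g]], path_g, expanded$pos)
    n_nonrep <- n_nonrep + sum(is.na(rep_pos))
    expanded <- expanded[!is.na(rep_pos), , drop = FALSE]
    expanded$pos <- rep_pos[!is.na(rep_pos)]
    if (!nrow(expanded)) next
    eff <- annotate_effects(expanded, orfs[[g]], rep_seqs[[g]])
    if (nrow(eff)) {
      eff$gene_id <- g
      eff_all[[length(eff_all) + 1L]] <- eff
    }
  }
  effects <- if (length(eff_all)) do.call(rbind, eff_all) else {
    e <- empty_effects(); e$gene_id <- character(0); e
  }
  paths$effects <- file.path(outdir, "effects.tsv")
  write_tsv(effects, paths$effects)
  orf_nt <- vapply(names(models)[valid], function(g)
    orf_cds(orfs[[g]], rep_seqs[[g]]), character(1))
  usage <- compute_codon_usage(orf_nt)
  paths$codon_usage <- file.path(outdir, "codon_usage.tsv")
  write_tsv(usage, paths$codon_usage)
  neut_uniform <- neutral_substitution_probability(NULL, mode = "exact")
  wts <- setNames(usage$count, usage$codon)
  neut_usage <- if (sum(wts) > 0)
    neutral_substitution_probability(wts, mode = "exact") else neut_uniform
  bias <- suppressWarnings(codon_position_bias(effects))
  summary$n_valid_orfs <- sum(valid)
  summary$n_effects <- nrow(effects)
  summary$n_nonrepresentative <- n_nonrep
  summary$frac_nonsynonymous <- if (nrow(effects))
    mean(effects$effect[effects$class == "SNP"] != "synonymous coding")
  else NA_real_
  summary$neutral_prob_uniform <- neut_uniform$probability
  summary$neutral_prob_usage <- neut_usage$probability
  summary$codon_position_bias <- as.list(bias)
  stage_log("orf", "%d valid ORFs, %d coding effects, neutral P(change)=%.3f",
            summary$n_valid_orfs, summary$n_effects, neut_usage$probability)

  # --- k-mer spectrum -------------------------------------------------------
  spec <- kmer_spectrum(c(reads$short$seq1, reads$short$seq2), config$kmer_k)
  shape <- classify_spectrum(spec)
  paths$kmer_hist <- file.path(outdir, "kmer_histogram.tsv")
  write_tsv(spec$histogram, paths$kmer_hist)
  paths$kmer_shape <- file.path(outdir, "kmer_shape.json")
  jsonlite::write_json(list(k = spec$k,
                            classification = shape$classification,
                            peaks = shape$peaks,
                            noise_boundary = shape$noise_boundary),
                       paths$kmer_shape, auto_unbox = TRUE, null = "null")
  summary$kmer_shape <- shape$classification
  stage_log("kmer", "k=%d spectrum: %s", spec$k, shape$classification)

  # --- category bias + differential expression ------------------------------
  ann_args <- config$annotation
  ann_args$models <- models
  ann_args$seed <- ann_args$seed %||% config$sim$seed
  annotation <- do.call(simulate_annotation, ann_args)
  paths$annotation <- file.path(outdir, "annotation.tsv")
  write_tsv(annotation, paths$annotation)
  sets <- classify_mutation_load(dens$per_gene, annotation)
  biast <- category_bias(sets$high, sets$zero, annotation)
  paths$category_bias <- file.path(outdir, "category_bias.tsv")
  write_tsv(biast, paths$category_bias)
  summary$n_high_load <- length(sets$high)
  summary$n_zero_load <- length(sets$zero)

  # null split: halve the mapped read pairs into pseudo-libraries A and B
  de_counts <- withr::with_seed(config$sim$seed + 505L, {
    aln <- mapped$alignments[!mapped$alignments$ambiguous, , drop = FALSE]
    pair_id <- sub("/[12]$", "", aln$read_id)
    pairs <- unique(pair_id)
    in_a <- pairs[runif(length(pairs)) < 0.5]
    a <- count_reads(aln[pair_id %in% in_a, , drop = FALSE],
                     gene_ids = names(refs))
    b <- count_reads(aln[!(pair_id %in% in_a), , drop = FALSE],
                     gene_ids = names(refs))
    data.frame(gene_id = a$gene_id, count_a = a$count, count_b = b$count,
               annotated = annotation$annotated[
                 match(a$gene_id, annotation$gene_id)],
               stringsAsFactors = FALSE)
  })
  de_args <- config$de
  de_args$counts <- de_counts
  de <- do.call(differential_expression, de_args)
  paths$de <- file.path(outdir, "differential_expression.tsv")
  write_tsv(de, paths$de)
  summary$n_de_significant <- sum(de$significant)
  stage_log("genestats", "%d high-load, %d zero-load, %d DE-significant",
            summary$n_high_load, summary$n_zero_load,
            summary$n_de_significant)

  manifest <- list(
    tool = "clonemut",
    version = as.character(utils::packageVersion("clonemut")),
    seed = config$sim$seed,
    config = config_snapshot(config),
    paths = lapply(paths, normalizePath),
    summary = summary
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

config_snapshot <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.data.frame(v)) as.list(v) else v)
  }
  list(sim = strip(config$sim), filter = strip(config$filter),
       scoring = strip(config$scoring), kmer_k = config$kmer_k,
       annotation = config$annotation, de = config$de)
}

# one row per alternate allele of SNP/indel call records
expand_call_alleles <- function(calls) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    alts <- strsplit(v$alt, ",", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      pos = rep(v$pos, length(alts)), ref = v$ref, alt = alts,
      class = v$class, indel_len = if (v$class == "deletion") 1L else
        NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
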
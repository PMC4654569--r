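#' Simulate multi-exon gene loci with alternatively spliced isoforms
#'
#' Each locus is an ordered set of exons plus a set of isoforms, every isoform
#' being a strictly increasing subsequence of the exon indices. The first
#' isoform always contains all exons, so the union of isoforms covers the
#' locus and the concatenation of all exons is the locus's full "genomic
#' order" sequence (the truth the Reference Gene Model should reconstruct).
#'
#' @param config a [sim_config()] object.
#' @return list of loci; each locus is a list with `gene_id`, `exons`
#'   (character vector of exon sequences) and `isoforms` (data frame with
#'   `isoform_id`, list-column `exon_idx`, and `weight`).
#' @export
simulate_loci <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 101L, {
    lapply(seq_len(config$n_genes), function(g) {
      gene_id <- sprintf("g%03d", g)
      n_exon <- sample_range(config$exon_count_range)
      exon_len <- vapply(seq_len(n_exon), function(i)
        sample_range(config$exon_length_range), integer(1))
      exons <- vapply(exon_len, random_dna, character(1))
      n_iso <- max(1L, sample_range(config$n_isoform_range))
      paths <- vector("list", n_iso)
      paths[[1L]] <- seq_len(n_exon)
      if (n_iso > 1L) {
        for (i in 2:n_iso) {
          if (n_exon == 1L) {
            paths[[i]] <- 1L
          } else {
            k <- sample_range(c(1L, n_exon - 1L))
            paths[[i]] <- sort(sample(seq_len(n_exon), k))
          }
        }
      }
      isoforms <- data.frame(
        isoform_id = sprintf("%s_i%d", gene_id, seq_len(n_iso)),
        weight = round(runif(n_iso, 0.5, 2), 3),
        stringsAsFactors = FALSE
      )
      isoforms$exon_idx <- paths
      list(gene_id = gene_id, exons = exons, isoforms = isoforms)
    })
  })
}

sample_range <- function(r) {
  if (r[1] == r[2]) return(as.integer(r[1]))
  as.integer(sample(seq.int(r[1], r[2]), 1L))
}

#' Full concatenated-exon sequence of a simulated locus
#' @param locus one element of [simulate_loci()]'s result.
#' @return single DNA string (all exons in genomic order).
#' @export
locus_sequence <- function(locus) paste(locus$exons, collapse = "")

#' Spliced sequence of one isoform of a simulated locus
#' @param locus a simulated locus.
#' @param i isoform index within `locus$isoforms`.
#' @return single DNA string.
#' @export
isoform_sequence <- function(locus, i) {
  paste(locus$exons[locus$isoforms$exon_idx[[i]]], collapse = "")
}

# cumulative exon start offsets (0-based) in concatenated-exon coordinates
exon_offsets <- function(locus) {
  len <- nchar(locus$exons)
  c(0L, cumsum(len))[seq_along(len)]
}

# map a concatenated-exon position (0-based) to a 0-based position on
# isoform i, or NA if the position's exon is absent from the isoform
concat_to_isoform_pos <- function(locus, i, pos) {
  len <- nchar(locus$exons)
  starts <- exon_offsets(locus)
  exon <- findInterval(pos, starts)
  path <- locus$isoforms$exon_idx[[i]]
  out <- rep(NA_integer_, length(pos))
  hit <- exon %in% path
  if (any(hit)) {
    iso_starts <- c(0L, cumsum(len[path]))[seq_along(path)]
    idx_in_path <- match(exon[hit], path)
    out[hit] <- iso_starts[idx_in_path] + (pos[hit] - starts[exon[hit]])
  }
  out
}
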
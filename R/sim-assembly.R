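#' Emulate an overlap-assembler's contig graph for simulated loci
#'
#' Produces the assembly-side view of the simulated loci the way an
#' overlap-consensus assembler reports isoform structure: one contig per
#' exon, per-gene directed edges recording every exon adjacency observed in
#' an isoform, one isotig (contig path) per isoform, and an isogroup table
#' mapping isotigs to genes. The per-gene graph is a DAG by construction
#' since exon indices increase along every isoform.
#'
#' @param loci result of [simulate_loci()].
#' @return a [contig_graph()] object.
#' @export
simulate_assembly <- function(loci) {
  contigs <- character(0)
  edge_rows <- list(); isotig_rows <- list()
  for (locus in loci) {
    gid <- locus$gene_id
    cids <- sprintf("%s_c%02d", gid, seq_along(locus$exons))
    contigs[cids] <- locus$exons
    seen <- character(0)
    for (i in seq_len(nrow(locus$isoforms))) {
      path <- locus$isoforms$exon_idx[[i]]
      if (length(path) > 1L) {
        from <- cids[path[-length(path)]]
        to <- cids[path[-1L]]
        key <- paste(from, to)
        new <- !(key %in% seen)
        seen <- c(seen, key[new])
        if (any(new))
          edge_rows[[length(edge_rows) + 1L]] <-
            data.frame(gene_id = gid, from = from[new], to = to[new],
                       stringsAsFactors = FALSE)
      }
      isotig_rows[[length(isotig_rows) + 1L]] <- list(
        gene_id = gid,
        isotig_id = sub("_i", "_t", locus$isoforms$isoform_id[i]),
        path = cids[path],
        sequence = isoform_sequence(locus, i)
      )
    }
  }
  edges <- rbind_or_empty(edge_rows, c(gene_id = "character",
                                       from = "character", to = "character"))
  isotigs <- data.frame(
    gene_id = vapply(isotig_rows, `[[`, character(1), "gene_id"),
    isotig_id = vapply(isotig_rows, `[[`, character(1), "isotig_id"),
    sequence = vapply(isotig_rows, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE
  )
  isotigs$path <- lapply(isotig_rows, `[[`, "path")
  contig_genes <- sub("_c[0-9]+$", "", names(contigs))
  contig_graph(
    contigs = contigs,
    contig_gene = setNames(contig_genes, names(contigs)),
    edges = edges,
    isotigs = isotigs
  )
}
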
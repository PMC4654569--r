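#' Assemble-side contig graph container
#'
#' Bundles the four assembly artifacts the Reference Gene Model is built
#' from: contig sequences, contig-to-gene (isogroup) membership, directed
#' adjacency edges between contigs of the same gene, and isotig paths (the
#' ordered contig list of each isoform, with its assembled sequence).
#'
#' @param contigs named character vector of contig sequences.
#' @param contig_gene named character vector mapping contig id to gene id.
#' @param edges data frame with columns `gene_id`, `from`, `to`.
#' @param isotigs data frame with columns `gene_id`, `isotig_id`,
#'   `sequence` and list-column `path` (ordered contig ids).
#' @return validated object of class `clonemut_contig_graph`.
#' @export
contig_graph <- function(contigs, contig_gene, edges, isotigs) {
  if (length(contigs) == 0L) input_error("contig set is empty")
  if (any(nchar(contigs) == 0L)) input_error("contigs must be non-empty")
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    input_error("contigs must be uniquely named")
  missing <- setdiff(names(contig_gene), names(contigs))
  if (length(missing))
    input_error(paste("membership refers to unknown contigs:",
                      paste(missing, collapse = ", ")))
  bad <- setdiff(c(edges$from, edges$to), names(contigs))
  if (length(bad))
    input_error(paste("graph edges refer to unknown contigs:",
                      paste(unique(bad), collapse = ", ")))
  for (i in seq_len(nrow(isotigs))) {
    p <- isotigs$path[[i]]
    absent <- setdiff(p, names(contigs))
    if (length(absent))
      input_error(sprintf("isotig %s path refers to missing contig(s): %s",
                          isotigs$isotig_id[i], paste(absent, collapse = ", ")))
  }
  g <- structure(list(contigs = contigs, contig_gene = contig_gene,
                      edges = edges, isotigs = isotigs),
                 class = "clonemut_contig_graph")
  for (gid in unique(isotigs$gene_id)) {
    sub <- gene_subgraph(g, gid)
    if (nrow(sub$edges) &&
        !igraph::is_dag(igraph::graph_from_data_frame(
          sub$edges[, c("from", "to")], vertices = sub$contig_ids)))
      graph_error(sprintf("contig graph of gene %s contains a cycle", gid))
  }
  g
}

#' @export
print.clonemut_contig_graph <- function(x, ...) {
  cat(sprintf("<contig graph: %d contigs, %d edges, %d isotigs, %d genes>\n",
              length(x$contigs), nrow(x$edges), nrow(x$isotigs),
              length(unique(x$contig_gene))))
  invisible(x)
}

gene_subgraph <- function(graph, gene_id) {
  cids <- names(graph$contig_gene)[graph$contig_gene == gene_id]
  iso <- graph$isotigs[graph$isotigs$gene_id == gene_id, , drop = FALSE]
  cids <- union(cids, unlist(iso$path))
  list(contig_ids = cids,
       edges = graph$edges[graph$edges$gene_id == gene_id, , drop = FALSE],
       isotigs = iso)
}

#' Linearize one gene's contig graph into a Reference Gene Model
#'
#' Orders the gene's contigs by a deterministic topological sort of its
#' contig graph and concatenates them (no spacer bases) into a single
#' intron-less virtual gene sequence, recording each contig's half-open
#' interval on it. Ties in the topological order are broken by the number of
#' isotig paths a contig participates in (descending) and then by contig id;
#' disconnected components are emitted in order of their smallest contig id;
#' contigs on no isotig path are appended last, in lexicographic order, and
#' flagged as orphans.
#'
#' @param graph a [contig_graph()].
#' @param gene_id the gene (isogroup) to linearize.
#' @return object of class `clonemut_reference_gene`: list with `gene_id`,
#'   `virtual_sequence`, `offsets` (data frame contig_id/start/end, 0-based
#'   half-open), `linear_order`, `orphans`, `n_components` and
#'   `representative_isotig_id` (NA until [select_representative()] is run).
#' @export
linearize_gene <- function(graph, gene_id) {
  sub <- gene_subgraph(graph, gene_id)
  if (length(sub$contig_ids) == 0L)
    input_error(sprintf("gene %s has no contigs", gene_id))

  path_contigs <- unique(unlist(sub$isotigs$path))
  path_count <- table(unlist(lapply(sub$isotigs$path, unique)))
  orphans <- sort(setdiff(sub$contig_ids, path_contigs))

  order_core <- character(0)
  if (length(path_contigs)) {
    edges <- sub$edges[sub$edges$from %in% path_contigs &
                       sub$edges$to %in% path_contigs, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                        vertices = path_contigs)
    comp <- igraph::components(ig, mode = "weak")
    comp_of <- comp$membership[path_contigs]
    comp_rank <- rank(vapply(split(path_contigs, comp_of),
                             min, character(1)))
    for (ci in names(sort(comp_rank))) {
      nodes <- path_contigs[comp_of == as.integer(ci)]
      order_core <- c(order_core,
                      kahn_order(nodes, edges, path_count, gene_id))
    }
  }
  linear_order <- c(order_core, orphans)
  seqs <- graph$contigs[linear_order]
  lens <- nchar(seqs)
  starts <- c(0L, cumsum(lens))[seq_along(lens)]
  structure(list(
    gene_id = gene_id,
    virtual_sequence = paste(seqs, collapse = ""),
    offsets = data.frame(contig_id = linear_order,
                         start = as.integer(starts),
                         end = as.integer(starts + lens),
                         stringsAsFactors = FALSE),
    linear_order = linear_order,
    orphans = orphans,
    n_components = if (length(path_contigs))
      length(unique(comp_of)) else 0L,
    representative_isotig_id = NA_character_
  ), class = "clonemut_reference_gene")
}

# Kahn's algorithm with deterministic tie-break:
# most incident isotig paths first, then lexicographic contig id
kahn_order <- function(nodes, edges, path_count, gene_id) {
  edges <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  edges <- unique(edges[, c("from", "to")])
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  pc <- setNames(rep(0L, length(nodes)), nodes)
  hit <- intersect(names(path_count), nodes)
  pc[hit] <- as.integer(path_count[hit])
  out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    ready <- ready[order(-pc[ready], ready)]
    nxt <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, nxt)
    succ <- edges$to[edges$from == nxt]
    for (s in succ) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) ready <- c(ready, s)
    }
  }
  if (length(out) != length(nodes))
    graph_error(sprintf("contig graph of gene %s contains a cycle", gene_id))
  out
}

#' Build Reference Gene Models for every gene in a contig graph
#'
#' @param graph a [contig_graph()].
#' @param scores optional named numeric vector of per-isotig homology scores
#'   used by [select_representative()].
#' @return named list of `clonemut_reference_gene` objects.
#' @export
build_gene_models <- function(graph, scores = NULL) {
  gids <- sort(unique(c(graph$contig_gene, graph$isotigs$gene_id)))
  models <- lapply(gids, function(gid) {
    m <- linearize_gene(graph, gid)
    m$representative_isotig_id <-
      select_representative(gid, graph$isotigs, scores)
    m
  })
  setNames(models, gids)
}

#' Select a gene's representative isotig
#'
#' The isotig with the highest homology score represents the gene; ties are
#' broken by sequence length (longest first) and then by isotig id. With no
#' scored isotig at all, the longest isotig is used and a warning emitted.
#'
#' @param gene_id gene to pick a representative for.
#' @param isotigs isotig table (as in [contig_graph()]).
#' @param scores named numeric vector isotig_id -> score, or NULL.
#' @return the representative isotig id.
#' @export
select_representative <- function(gene_id, isotigs, scores = NULL) {
  cand <- isotigs[isotigs$gene_id == gene_id, , drop = FALSE]
  if (nrow(cand) == 0L)
    input_error(sprintf("gene %s has no isotigs", gene_id))
  len <- nchar(cand$sequence)
  sc <- rep(NA_real_, nrow(cand))
  if (!is.null(scores)) sc <- unname(scores[cand$isotig_id])
  if (all(is.na(sc))) {
    warning(sprintf("gene %s: no scored isotig; falling back to longest",
                    gene_id), call. = FALSE)
    sc <- rep(0, nrow(cand))
  }
  sc[is.na(sc)] <- -Inf
  ord <- order(-sc, -len, cand$isotig_id)
  cand$isotig_id[ord[1L]]
}

#' Map a model position onto an isotig
#'
#' Inverts the concatenation bookkeeping of [linearize_gene()]: a 0-based
#' position on the virtual gene sequence is translated to the 0-based
#' position on the spliced isotig whose contig path is given. Positions in
#' contigs the isotig lacks return `NA` (the "not in isotig" sentinel).
#'
#' @param ref a `clonemut_reference_gene`.
#' @param isotig_path ordered character vector of contig ids.
#' @param model_pos integer vector of 0-based model positions.
#' @return integer vector of isotig positions (NA where not covered).
#' @export
model_to_isotig_coords <- function(ref, isotig_path, model_pos) {
  n <- nchar(ref$virtual_sequence)
  if (any(model_pos < 0L | model_pos >= n))
    bounds_error(sprintf("model position out of range [0, %d)", n))
  off <- ref$offsets
  idx <- findInterval(model_pos, off$start)
  contig <- off$contig_id[idx]
  in_path <- contig %in% isotig_path
  out <- rep(NA_integer_, length(model_pos))
  if (any(in_path)) {
    clen <- off$end - off$start
    names(clen) <- off$contig_id
    path_starts <- c(0L, cumsum(clen[isotig_path]))[seq_along(isotig_path)]
    names(path_starts) <- isotig_path
    out[in_path] <- as.integer(path_starts[contig[in_path]] +
      (model_pos[in_path] - off$start[idx[in_path]]))
  }
  out
}
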
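#' Local-alignment scoring parameters
#'
#' Conventional local-alignment defaults: match +1, mismatch -2, gap open
#' -4, gap extend -1 (a length-L gap costs open + L x extend), seed length
#' 15 for candidate-gene lookup, and a minimum reported score of 30.
#'
#' @param match,mismatch,gap_open,gap_extend scoring terms; penalties are
#'   positive numbers.
#' @param min_seed k-mer length used to shortlist candidate references; reads
#'   shorter than this are reported unmapped.
#' @param min_score alignments scoring below this are discarded.
#' @param trim_to optional 5' hard-trim length applied to short-read
#'   libraries before mapping (mirrors trimming reads to their first 200
#'   bases); NULL disables.
#' @return list of class `clonemut_scoring_params`.
#' @export
scoring_params <- function(match = 1, mismatch = 2, gap_open = 4,
                           gap_extend = 1, min_seed = 15L, min_score = 30,
                           trim_to = 200L) {
  if (match <= 0 || mismatch <= 0 || gap_open <= 0 || gap_extend <= 0)
    config_error("match reward and all penalties must be > 0")
  if (min_seed < 4L) config_error("min_seed must be >= 4")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_seed = as.integer(min_seed),
                 min_score = min_score,
                 trim_to = if (is.null(trim_to)) NULL else as.integer(trim_to)),
            class = "clonemut_scoring_params")
}

#' Optimal local alignment of one read against one reference
#'
#' Full affine-gap Smith-Waterman dynamic programming (the exon-gap-tolerant
#' aligner of the pipeline: a read from an isoform missing an internal exon
#' aligns across the exon's contig with a reference deletion, or as a
#' clipped local hit, whichever scores higher).
#'
#' @param read,reference DNA strings.
#' @param params a [scoring_params()].
#' @return one-row data frame (score, read_start/read_end and
#'   ref_start/ref_end as 0-based half-open intervals, cigar with soft
#'   clips, nm = edit distance of the aligned region), or NULL when the read
#'   is shorter than `min_seed` or no alignment reaches `min_score`.
#' @export
local_align <- function(read, reference, params = scoring_params()) {
  if (!nzchar(read) || !nzchar(reference))
    input_error("read and reference must be non-empty")
  if (nchar(read) < params$min_seed) return(NULL)
  hit <- .sw_align_batch(read, reference, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
  if (hit$score[1] < params$min_score) return(NULL)
  hit
}

# k-mer index of the reference set: every k-mer of every reference,
# matched against read seeds with base::match (hash join)
build_seed_index <- function(references, k) {
  stopifnot(length(references) > 0L)
  kmers <- lapply(references, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  })
  data.frame(kmer = unlist(kmers, use.names = FALSE),
             ref = rep(names(references), lengths(kmers)),
             stringsAsFactors = FALSE)
}

seed_candidates <- function(seq, index, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  at <- unique(c(seq(1L, n - k + 1L, by = k), n - k + 1L))
  seeds <- substring(seq, at, at + k - 1L)
  unique(index$ref[index$kmer %in% seeds])
}

#' Map reads to a reference set and report the mapping rate
#'
#' Seed-and-extend: `min_seed`-mers of each read (and of its reverse
#' complement) shortlist candidate references via an exact k-mer index; each
#' candidate is then aligned with full Smith-Waterman dynamic programming,
#' so reported scores equal exhaustive-DP scores. Each read is assigned to
#' the highest-scoring reference; reads tying across references are flagged
#' ambiguous (and excluded from downstream counting and pileups), ties
#' within a reference keep the first (leftmost) hit.
#'
#' @param reads named character vector of read sequences (names = read ids),
#'   or a data frame with columns `read_id` and `seq`.
#' @param references named character vector of reference sequences (e.g.
#'   Reference Gene Model virtual sequences, one per gene).
#' @param params a [scoring_params()]; `trim_to`, when set and
#'   `trim = TRUE`, hard-trims reads to their first `trim_to` bases.
#' @param trim whether to apply the 5' hard trim (default TRUE, the
#'   short-read behaviour; set FALSE for long reads).
#' @return list with `alignments` (data frame: read_id, gene_id, start, end,
#'   strand, cigar, score, nm, ambiguous) holding the best alignment per
#'   mapped read, and `mapping_rate` = mapped reads / total reads.
#' @export
map_reads <- function(reads, references, params = scoring_params(),
                      trim = TRUE) {
  if (length(references) == 0L) input_error("empty reference set")
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (length(reads) == 0L)
    return(list(alignments = empty_alignments(), mapping_rate = NaN))
  if (trim && !is.null(params$trim_to))
    reads <- ifelse(nchar(reads) > params$trim_to,
                    substr(reads, 1L, params$trim_to), reads)
  k <- params$min_seed
  index <- build_seed_index(references, k)
  rc <- revcomp_chr(reads)

  # jobs: (read index, reference, strand)
  job_read <- integer(0); job_ref <- character(0); job_strand <- character(0)
  for (i in seq_along(reads)) {
    if (nchar(reads[[i]]) < k) next
    fwd <- seed_candidates(reads[[i]], index, k)
    rev <- seed_candidates(rc[[i]], index, k)
    if (length(fwd)) {
      job_read <- c(job_read, rep(i, length(fwd)))
      job_ref <- c(job_ref, fwd)
      job_strand <- c(job_strand, rep("+", length(fwd)))
    }
    if (length(rev)) {
      job_read <- c(job_read, rep(i, length(rev)))
      job_ref <- c(job_ref, rev)
      job_strand <- c(job_strand, rep("-", length(rev)))
    }
  }
  if (length(job_read) == 0L)
    return(list(alignments = empty_alignments(), mapping_rate = 0))

  hits <- vector("list", length(unique(paste(job_ref, job_strand))))
  hi <- 0L
  for (ref_id in unique(job_ref)) {
    for (strand in c("+", "-")) {
      sel <- which(job_ref == ref_id & job_strand == strand)
      if (!length(sel)) next
      seqs <- if (strand == "+") reads[job_read[sel]] else rc[job_read[sel]]
      res <- .sw_align_batch(unname(seqs), references[[ref_id]],
                             params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
      res$read_idx <- job_read[sel]
      res$gene_id <- ref_id
      res$strand <- strand
      hi <- hi + 1L
      hits[[hi]] <- res
    }
  }
  hits <- do.call(rbind, hits[seq_len(hi)])
  hits <- hits[hits$score >= params$min_score, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(alignments = empty_alignments(), mapping_rate = 0))

  # best hit per read; ambiguity = equal best score on a second reference
  best <- lapply(split(hits, hits$read_idx), function(h) {
    top <- max(h$score)
    th <- h[h$score == top, , drop = FALSE]
    amb <- length(unique(th$gene_id)) > 1L
    th <- th[order(th$gene_id, th$strand, th$ref_start), , drop = FALSE]
    cbind(th[1L, , drop = FALSE], ambiguous = amb)
  })
  best <- do.call(rbind, best)
  aln <- data.frame(
    read_id = names(reads)[best$read_idx],
    gene_id = best$gene_id,
    start = best$ref_start,
    end = best$ref_end,
    strand = best$strand,
    cigar = best$cigar,
    score = best$score,
    nm = best$nm,
    read_start = best$read_start,
    read_end = best$read_end,
    ambiguous = best$ambiguous,
    stringsAsFactors = FALSE
  )
  rownames(aln) <- NULL
  list(alignments = aln, mapping_rate = nrow(aln) / length(reads))
}

empty_alignments <- function() {
  data.frame(read_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             cigar = character(0), score = numeric(0), nm = integer(0),
             read_start = integer(0), read_end = integer(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}

#' Count mapped reads per gene
#'
#' Reads mapped to a Reference Gene Model land on one reference per gene,
#' so a read is counted once for its gene regardless of which isoforms
#' share its exons (the multi-mapping problem the model removes).
#' Ambiguously mapped reads (equal best score on several genes) are
#' excluded from `count` and reported in `ambiguous_count`.
#'
#' @param alignments alignment table from [map_reads()].
#' @param gene_ids optional character vector of genes to report (zero rows
#'   are kept for genes without reads).
#' @param gene_of optional named character vector mapping reference id to
#'   gene id (the isogroup table); used when alignments were made against
#'   isotig references rather than gene models. In that "control" mode a
#'   read tying across isotigs of one gene is still one gene-level count,
#'   but note [map_reads()] retains a single best hit -- to reproduce the
#'   double-counting of per-isotig counting, see [count_reads_per_isotig()].
#' @return data frame gene_id, count, ambiguous_count.
#' @export
count_reads <- function(alignments, gene_ids = NULL, gene_of = NULL) {
  aln <- alignments
  if (!is.null(gene_of)) aln$gene_id <- unname(gene_of[aln$gene_id])
  genes <- gene_ids %||% sort(unique(aln$gene_id))
  counted <- table(factor(aln$gene_id[!aln$ambiguous], levels = genes))
  amb <- table(factor(aln$gene_id[aln$ambiguous], levels = genes))
  data.frame(gene_id = genes,
             count = as.integer(counted),
             ambiguous_count = as.integer(amb),
             stringsAsFactors = FALSE)
}

#' Per-isotig counting against the raw isotig set (control mode)
#'
#' The comparison mode motivating the Reference Gene Model: reads are
#' aligned against every isotig and each isotig that achieves the read's
#' best score receives a count; per-gene totals are the sum over the gene's
#' isotigs. Reads from exons shared among a gene's isoforms are therefore
#' counted multiple times.
#'
#' @param reads,params as in [map_reads()].
#' @param isotigs isotig table of a [contig_graph()] (gene_id, isotig_id,
#'   sequence).
#' @param trim as in [map_reads()].
#' @return data frame gene_id, count (sum over isotigs of best-score hits).
#' @export
count_reads_per_isotig <- function(reads, isotigs, params = scoring_params(),
                                   trim = TRUE) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (trim && !is.null(params$trim_to))
    reads <- ifelse(nchar(reads) > params$trim_to,
                    substr(reads, 1L, params$trim_to), reads)
  refs <- setNames(isotigs$sequence, isotigs$isotig_id)
  k <- params$min_seed
  index <- build_seed_index(refs, k)
  rc <- revcomp_chr(reads)
  per_isotig <- setNames(integer(nrow(isotigs)), isotigs$isotig_id)
  for (i in seq_along(reads)) {
    if (nchar(reads[[i]]) < k) next
    cand <- union(seed_candidates(reads[[i]], index, k),
                  seed_candidates(rc[[i]], index, k))
    if (!length(cand)) next
    sc <- vapply(cand, function(tid) {
      max(.sw_align_batch(c(reads[[i]], rc[[i]]), refs[[tid]],
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend)$score)
    }, numeric(1))
    top <- max(sc)
    if (top < params$min_score) next
    winners <- cand[sc == top]
    per_isotig[winners] <- per_isotig[winners] + 1L
  }
  agg <- tapply(per_isotig, isotigs$gene_id, sum)
  data.frame(gene_id = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE)
}
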
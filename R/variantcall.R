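#' Variant filter configuration
#'
#' Defaults implement the clonal-strain SNP filter: a site is kept only when
#' an alternate allele's fraction falls in the retained windows
#' \[0.06, 0.30\] or \[0.70, 0.94\] (closed intervals; fractions near 0.5
#' are ancestral heterozygosity, fractions near 1.0 reflect cross-platform
#' reference bias) and read depth is at least 3. A minimum alternate-allele
#' count of 2 suppresses singleton sequencing errors.
#'
#' @param windows list of length-2 numeric vectors: retained allelic
#'   fraction windows (closed).
#' @param min_depth minimum site depth for PASS.
#' @param min_alt_count minimum observations of an alternate allele for the
#'   allele to be called at all.
#' @param hom_threshold max alt fraction at or above which a call is
#'   classified homozygous rather than heterozygous.
#' @param filter_indels apply the fraction windows to InDel records too
#'   (default FALSE: windows are a SNP-rate filter; InDels only face the
#'   depth rule).
#' @param indel_mask_bp SNP calls within this many bases of a called InDel
#'   are dropped (cheap surrogate for local realignment).
#' @return list of class `clonemut_filter_config`.
#' @export
filter_config <- function(windows = list(c(0.06, 0.30), c(0.70, 0.94)),
                          min_depth = 3L, min_alt_count = 2L,
                          hom_threshold = 0.95, filter_indels = FALSE,
                          indel_mask_bp = 5L) {
  for (w in windows)
    if (length(w) != 2L || w[1] <= 0 || w[2] >= 1 || w[1] > w[2])
      config_error("each retained window must be (lo, hi) with 0 < lo <= hi < 1")
  if (length(windows) > 1L) {
    m <- do.call(rbind, windows[order(vapply(windows, `[`, numeric(1), 1))])
    if (any(m[-1L, 1] <= m[-nrow(m), 2]))
      config_error("retained windows must not overlap")
  }
  if (min_depth < 1L || min_alt_count < 1L)
    config_error("min_depth and min_alt_count must be >= 1")
  structure(list(windows = windows, min_depth = as.integer(min_depth),
                 min_alt_count = as.integer(min_alt_count),
                 hom_threshold = hom_threshold,
                 filter_indels = isTRUE(filter_indels),
                 indel_mask_bp = as.integer(indel_mask_bp)),
            class = "clonemut_filter_config")
}

#' Build per-gene pileups from alignments
#'
#' Tallies, for every covered reference position, the aligned read bases
#' (A/C/G/T), deletion observations (a read whose alignment deletes the
#' position), and insertion observations (attributed to the reference
#' position preceding the inserted sequence). Ambiguously mapped reads are
#' excluded.
#'
#' @param alignments alignment table from [map_reads()].
#' @param reads the read sequences the alignments refer to (named character
#'   vector or data frame with read_id/seq). Reads are re-trimmed with
#'   `trim_to` when `trim = TRUE` so bases match what was aligned.
#' @param references named character vector of reference sequences.
#' @param params the [scoring_params()] used for mapping (for `trim_to`).
#' @param trim whether reads were 5'-trimmed at mapping time.
#' @return list with `columns` (data frame: gene_id, pos (0-based), ref,
#'   A, C, G, T, del, depth) for positions with depth > 0, and `insertions`
#'   (gene_id, pos, seq, count).
#' @export
build_pileup <- function(alignments, reads, references,
                         params = scoring_params(), trim = TRUE) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (trim && !is.null(params$trim_to))
    reads <- ifelse(nchar(reads) > params$trim_to,
                    substr(reads, 1L, params$trim_to), reads)
  aln <- alignments[!alignments$ambiguous, , drop = FALSE]
  pos_l <- vector("list", nrow(aln)); base_l <- vector("list", nrow(aln))
  gene_l <- vector("list", nrow(aln)); ins_l <- list()
  for (r in seq_len(nrow(aln))) {
    a <- aln[r, ]
    seq_used <- reads[[a$read_id]]
    if (a$strand == "-") seq_used <- revcomp_chr(seq_used)
    ops <- parse_cigar(a$cigar)
    rp <- a$start       # reference cursor, 0-based
    qp <- 0L            # read cursor, 0-based
    pp <- integer(0); bb <- character(0)
    for (k in seq_len(nrow(ops))) {
      len <- ops$len[k]
      switch(ops$op[k],
        "S" = { qp <- qp + len },
        "M" = {
          pp <- c(pp, rp:(rp + len - 1L))
          bb <- c(bb, strsplit(substr(seq_used, qp + 1L, qp + len),
                               "", fixed = TRUE)[[1L]])
          rp <- rp + len; qp <- qp + len
        },
        "D" = {
          pp <- c(pp, rp:(rp + len - 1L))
          bb <- c(bb, rep("-", len))
          rp <- rp + len
        },
        "I" = {
          ins_l[[length(ins_l) + 1L]] <- data.frame(
            gene_id = a$gene_id, pos = rp - 1L,
            seq = substr(seq_used, qp + 1L, qp + len),
            stringsAsFactors = FALSE)
          qp <- qp + len
        },
        input_error(sprintf("unsupported CIGAR op in %s", a$cigar)))
    }
    if (rp > nchar(references[[a$gene_id]]))
      input_error(sprintf("alignment of %s exceeds reference bounds",
                          a$read_id))
    pos_l[[r]] <- pp; base_l[[r]] <- bb
    gene_l[[r]] <- rep(a$gene_id, length(pp))
  }
  gene <- unlist(gene_l); pos <- unlist(pos_l); base <- unlist(base_l)
  if (length(gene) == 0L) {
    return(list(columns = empty_pileup(), insertions = empty_insertions()))
  }
  key <- paste(gene, pos)
  tab <- table(key, factor(base, levels = c(DNA_BASES, "-")))
  uk <- rownames(tab)
  sp <- strsplit(uk, " ", fixed = TRUE)
  g <- vapply(sp, `[`, character(1), 1L)
  p <- as.integer(vapply(sp, `[`, character(1), 2L))
  cols <- data.frame(gene_id = g, pos = p,
                     ref = substring(references[g], p + 1L, p + 1L),
                     A = as.integer(tab[, "A"]), C = as.integer(tab[, "C"]),
                     G = as.integer(tab[, "G"]), T = as.integer(tab[, "T"]),
                     del = as.integer(tab[, "-"]),
                     stringsAsFactors = FALSE)
  cols$depth <- cols$A + cols$C + cols$G + cols$T
  cols <- cols[order(cols$gene_id, cols$pos), , drop = FALSE]
  rownames(cols) <- NULL
  ins <- if (length(ins_l)) {
    allins <- do.call(rbind, ins_l)
    agg <- aggregate(list(count = rep(1L, nrow(allins))),
                     by = allins[c("gene_id", "pos", "seq")], FUN = sum)
    agg[order(agg$gene_id, agg$pos), , drop = FALSE]
  } else empty_insertions()
  rownames(ins) <- NULL
  list(columns = cols, insertions = ins)
}

empty_pileup <- function() {
  data.frame(gene_id = character(0), pos = integer(0), ref = character(0),
             A = integer(0), C = integer(0), G = integer(0), T = integer(0),
             del = integer(0), depth = integer(0), stringsAsFactors = FALSE)
}
empty_insertions <- function() {
  data.frame(gene_id = character(0), pos = integer(0), seq = character(0),
             count = integer(0), stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1L]]
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

#' Call variants from pileups (pre-filter)
#'
#' A site is called when any non-reference allele is observed at least
#' `min_alt_count` times. SNP records carry every substitution allele of
#' the site; deletion and insertion observations are called as separate
#' records of their own class. Zygosity is heterozygous when the maximum
#' alternate fraction is below `hom_threshold`, homozygous otherwise.
#' SNP records within `indel_mask_bp` of a called InDel on the same gene
#' are suppressed.
#'
#' @param pileup result of [build_pileup()].
#' @param config a [filter_config()].
#' @return data frame with one row per (site, class): gene_id, pos, ref,
#'   class ("SNP"/"deletion"/"insertion"), alt / alt_count / alt_fraction
#'   (comma-joined per allele), max_fraction, depth, zygosity, filter
#'   (initialized to ".").
#' @export
call_variants <- function(pileup, config = filter_config()) {
  cols <- pileup$columns
  out <- list()
  if (nrow(cols)) {
    cnt <- as.matrix(cols[, DNA_BASES])
    for (i in seq_len(nrow(cols))) {
      ref <- cols$ref[i]
      alt_bases <- setdiff(DNA_BASES, ref)
      ac <- cnt[i, alt_bases]
      keep <- ac >= config$min_alt_count
      depth <- cols$depth[i]
      if (any(keep)) {
        a <- alt_bases[keep]; n <- unname(ac[keep])
        fr <- n / depth
        out[[length(out) + 1L]] <- variant_row(cols$gene_id[i], cols$pos[i],
                                               ref, "SNP", a, n, fr, depth,
                                               config)
      }
      if (cols$del[i] >= config$min_alt_count) {
        dtot <- depth + cols$del[i]
        out[[length(out) + 1L]] <- variant_row(cols$gene_id[i], cols$pos[i],
                                               ref, "deletion", "-",
                                               cols$del[i],
                                               cols$del[i] / dtot, dtot,
                                               config)
      }
    }
  }
  ins <- pileup$insertions
  if (nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      if (ins$count[i] < config$min_alt_count) next
      col <- cols[cols$gene_id == ins$gene_id[i] & cols$pos == ins$pos[i], ]
      depth <- if (nrow(col)) col$depth[1L] else ins$count[i]
      out[[length(out) + 1L]] <- variant_row(ins$gene_id[i], ins$pos[i],
                                             if (nrow(col)) col$ref[1L] else "N",
                                             "insertion",
                                             paste0("+", ins$seq[i]),
                                             ins$count[i],
                                             ins$count[i] / depth, depth,
                                             config)
    }
  }
  calls <- rbind_or_empty(out, c(gene_id = "character", pos = "integer",
                                 ref = "character", class = "character",
                                 alt = "character", alt_count = "character",
                                 alt_fraction = "character",
                                 max_fraction = "numeric", depth = "integer",
                                 zygosity = "character", filter = "character"))
  calls <- calls[order(calls$gene_id, calls$pos, calls$class), , drop = FALSE]
  rownames(calls) <- NULL
  mask_near_indels(calls, config$indel_mask_bp)
}

variant_row <- function(gid, pos, ref, class, alts, counts, fracs, depth,
                        config) {
  data.frame(
    gene_id = gid, pos = as.integer(pos), ref = ref, class = class,
    alt = paste(alts, collapse = ","),
    alt_count = paste(counts, collapse = ","),
    alt_fraction = paste(signif(fracs, 6), collapse = ","),
    max_fraction = max(fracs),
    depth = as.integer(depth),
    zygosity = if (max(fracs) >= config$hom_threshold) "homozygous"
               else "heterozygous",
    filter = ".",
    stringsAsFactors = FALSE
  )
}

mask_near_indels <- function(calls, mask_bp) {
  if (!nrow(calls) || mask_bp <= 0L) return(calls)
  drop <- logical(nrow(calls))
  ind <- calls[calls$class != "SNP", c("gene_id", "pos")]
  if (nrow(ind)) {
    snp <- which(calls$class == "SNP")
    for (i in snp) {
      near <- ind$gene_id == calls$gene_id[i] &
        abs(ind$pos - calls$pos[i]) <= mask_bp & ind$pos != calls$pos[i]
      if (any(near)) drop[i] <- TRUE
    }
  }
  calls[!drop, , drop = FALSE]
}

parse_num_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.numeric)

#' Apply the clonal allelic-fraction and depth filter
#'
#' Sets the `filter` column of every call: `PASS` when depth is at least
#' `min_depth` and at least one alternate fraction lies inside a retained
#' window; otherwise `low_depth`, `low_fraction` (all fractions below the
#' lowest window) or `ancestral_or_platform` (fractions in the excluded
#' mid/high ranges: ancestral heterozygosity near 0.5 or platform bias
#' near 1.0). InDel records face only the depth rule unless
#' `config$filter_indels` is TRUE. The operation is idempotent.
#'
#' @param calls table from [call_variants()] (or its own output).
#' @param config a [filter_config()].
#' @return the calls with `filter` set.
#' @export
filter_clonal <- function(calls, config = filter_config()) {
  if (!nrow(calls)) return(calls)
  fr <- parse_num_list(calls$alt_fraction)
  lo_min <- min(vapply(config$windows, `[`, numeric(1), 1L))
  in_window <- vapply(fr, function(f)
    any(vapply(config$windows, function(w)
      any(f >= w[1] & f <= w[2]), logical(1))), logical(1))
  status <- character(nrow(calls))
  windowed <- calls$class == "SNP" | config$filter_indels
  for (i in seq_len(nrow(calls))) {
    if (calls$depth[i] < config$min_depth) {
      status[i] <- "low_depth"
    } else if (!windowed[i] || in_window[i]) {
      status[i] <- "PASS"
    } else if (all(fr[[i]] < lo_min)) {
      status[i] <- "low_fraction"
    } else {
      status[i] <- "ancestral_or_platform"
    }
  }
  calls$filter <- status
  calls
}

#' Per-gene SNP density and genome-wide rate
#'
#' Density is 1000 x (PASS SNP sites) / model length per gene; the
#' genome-wide rate uses total PASS SNPs over total length. The histogram
#' bins per-gene density at 1 SNP/kb.
#'
#' @param calls filtered calls ([filter_clonal()]).
#' @param gene_lengths named integer vector of model lengths (bp).
#' @return list with `per_gene` (gene_id, length, n_snps, snps_per_kb),
#'   `genome_rate` (SNPs per 1000 bp overall) and `histogram`
#'   (bin lower edge, n_genes).
#' @export
snp_density <- function(calls, gene_lengths) {
  if (any(gene_lengths <= 0)) input_error("gene lengths must be > 0")
  pass <- calls[calls$filter == "PASS" & calls$class == "SNP", , drop = FALSE]
  unknown <- setdiff(unique(pass$gene_id), names(gene_lengths))
  if (length(unknown))
    input_error(paste("calls for genes without a length:",
                      paste(unknown, collapse = ", ")))
  genes <- names(gene_lengths)
  n <- table(factor(pass$gene_id, levels = genes))
  per_gene <- data.frame(gene_id = genes,
                         length = as.integer(gene_lengths),
                         n_snps = as.integer(n),
                         stringsAsFactors = FALSE)
  per_gene$snps_per_kb <- 1000 * per_gene$n_snps / per_gene$length
  bins <- floor(per_gene$snps_per_kb)
  hist <- as.data.frame(table(bin = bins), stringsAsFactors = FALSE)
  names(hist) <- c("bin", "n_genes")
  hist$bin <- as.integer(hist$bin)
  list(per_gene = per_gene,
       genome_rate = 1000 * sum(per_gene$n_snps) / sum(per_gene$length),
       histogram = hist)
}
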
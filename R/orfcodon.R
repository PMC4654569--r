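#' Predict the longest open reading frame of a sequence
#'
#' Scans all six reading frames (1-3 forward, 4-6 reverse) for the longest
#' run of non-stop codons starting at an initiator ATG; the run ends at the
#' next stop codon or, for 3'-incomplete transcripts, at the last complete
#' codon of the frame. Only ORFs of at least `min_aa` amino acids
#' (initiator Met included; a 100-aa ORF passes the default threshold) are
#' reported. Ties are broken by the lowest frame number, then the leftmost
#' start within the frame.
#'
#' @param sequence DNA string.
#' @param min_aa minimum translated length in amino acids (default 100).
#' @param require_atg require an initiator ATG (default). With FALSE, any
#'   stop-to-stop stretch is eligible (open-ended mode).
#' @param frames `"both"` (default) or `"forward"` to restrict to frames
#'   1-3.
#' @return NULL when no qualifying ORF exists; otherwise a list with
#'   `frame` (1-6), `strand`, `start`/`end` (0-based half-open interval on
#'   the input's forward coordinates, stop codon excluded), `aa`
#'   (translation) and `aa_length`.
#' @export
predict_longest_orf <- function(sequence, min_aa = 100L, require_atg = TRUE,
                                frames = c("both", "forward")) {
  frames <- match.arg(frames)
  L <- nchar(sequence)
  if (L < 3L) return(NULL)
  strands <- list(`+` = sequence, `-` = revcomp_chr(sequence))
  if (frames == "forward") strands <- strands["+"]
  best <- NULL
  for (si in seq_along(strands)) {
    s <- strands[[si]]
    strand <- names(strands)[si]
    for (off in 0:2) {
      frame_no <- off + 1L + (si - 1L) * 3L
      n_codon <- (L - off) %/% 3L
      if (n_codon < 1L) next
      sub <- substr(s, off + 1L, off + 3L * n_codon)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(sub),
                              no.init.codon = TRUE)))
      cand <- frame_orfs(aa, require_atg)
      if (nrow(cand) == 0L) next
      cand <- cand[which.max(cand$len), ]
      if (cand$len < min_aa) next
      if (is.null(best) || cand$len > best$aa_length) {
        nt_start <- off + 3L * (cand$aa_start - 1L)      # 0-based on strand
        nt_end <- nt_start + 3L * cand$len
        if (strand == "+") {
          ivl <- c(nt_start, nt_end)
        } else {
          ivl <- c(L - nt_end, L - nt_start)
        }
        best <- list(frame = frame_no, strand = strand,
                     start = as.integer(ivl[1]), end = as.integer(ivl[2]),
                     aa = substr(aa, cand$aa_start,
                                 cand$aa_start + cand$len - 1L),
                     aa_length = cand$len)
      }
    }
  }
  best
}

# ORFs within one translated frame: data frame aa_start (1-based), len
frame_orfs <- function(aa, require_atg) {
  stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  bounds <- c(0L, if (stops[1] != -1L) as.integer(stops), nchar(aa) + 1L)
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    seg_start <- bounds[b] + 1L
    seg_end <- bounds[b + 1L] - 1L
    if (seg_end < seg_start) next
    if (require_atg) {
      seg <- substr(aa, seg_start, seg_end)
      m <- regexpr("M", seg, fixed = TRUE)
      if (m == -1L) next
      seg_start <- seg_start + as.integer(m) - 1L
    }
    out[[length(out) + 1L]] <-
      data.frame(aa_start = seg_start, len = seg_end - seg_start + 1L)
  }
  if (!length(out)) return(data.frame(aa_start = integer(0), len = integer(0)))
  do.call(rbind, out)
}

#' Codon usage table of a set of ORFs
#'
#' Tallies codons (reading-frame triplets) over the supplied coding
#' sequences and normalizes to relative frequencies.
#'
#' @param orf_sequences character vector of in-frame coding nucleotide
#'   sequences (lengths multiples of 3).
#' @return data frame with 64 rows: codon, count, frequency. With no input
#'   codons, counts are zero and frequencies NA (flagged by a warning).
#' @export
compute_codon_usage <- function(orf_sequences) {
  codons <- sort(all_codons())
  counts <- setNames(integer(64L), codons)
  if (length(orf_sequences)) {
    tf <- Biostrings::trinucleotideFrequency(
      Biostrings::DNAStringSet(orf_sequences), step = 3L)
    tot <- colSums(tf)
    counts[names(tot)] <- as.integer(tot)
  }
  total <- sum(counts)
  if (total == 0L)
    warning("no codons counted; frequencies undefined", call. = FALSE)
  data.frame(codon = codons, count = unname(counts),
             frequency = if (total > 0L) unname(counts) / total
                         else rep(NA_real_, 64L),
             stringsAsFactors = FALSE)
}

all_codons <- function() {
  grid <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                      stringsAsFactors = FALSE)
  paste0(grid[[3L]], grid[[2L]], grid[[1L]])
}

GENETIC_CODE_TABLE <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify coding effects of variants against an ORF
#'
#' SNPs inside the ORF are classified as synonymous coding, non-synonymous
#' coding or stop gained by translating the mutated codon. InDels inside
#' the ORF: length not divisible by 3 is a frame shift; in-frame InDels are
#' codon deletions/insertions when aligned to a codon boundary and
#' "codon change plus codon deletion/insertion" when straddling codons;
#' any in-frame InDel creating a premature stop is stop gained. Variants
#' outside the ORF yield no record.
#'
#' @param variants data frame with one row per alternate allele: `pos`
#'   (0-based position on `sequence`), `ref`, `alt` (a base for SNPs, "-"
#'   for deletions, "+SEQ" for insertions), `class` ("SNP", "deletion",
#'   "insertion") and optionally `indel_len` (deleted-base count, default 1).
#' @param orf result of [predict_longest_orf()] on `sequence`.
#' @param sequence the DNA sequence the positions refer to.
#' @return data frame: pos, ref, alt, class, effect, codon_pos (1-3 for
#'   in-ORF SNPs, NA otherwise), aa_ref, aa_alt.
#' @export
annotate_effects <- function(variants, orf, sequence) {
  if (is.null(orf) || nrow(variants) == 0L)
    return(empty_effects())
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    rec <- annotate_one_effect(v, orf, sequence)
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  rbind_or_empty(out, c(pos = "integer", ref = "character",
                        alt = "character", class = "character",
                        effect = "character", codon_pos = "integer",
                        aa_ref = "character", aa_alt = "character"))
}

empty_effects <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             class = character(0), effect = character(0),
             codon_pos = integer(0), aa_ref = character(0),
             aa_alt = character(0), stringsAsFactors = FALSE)
}

annotate_one_effect <- function(v, orf, sequence) {
  if (v$pos < 0L || v$pos >= nchar(sequence))
    bounds_error("variant position outside the annotated sequence")
  if (v$class == "SNP" &&
      substr(sequence, v$pos + 1L, v$pos + 1L) != v$ref)
    input_error(sprintf("reference allele mismatch at position %d", v$pos))
  if (v$pos < orf$start || v$pos >= orf$end) return(NULL)

  # coding-strand offset of the variant within the ORF
  if (orf$strand == "+") {
    off <- v$pos - orf$start
  } else {
    off <- (orf$end - 1L) - v$pos
  }
  cds <- orf_cds(orf, sequence)
  rec <- function(effect, codon_pos = NA_integer_, aa_ref = NA_character_,
                  aa_alt = NA_character_) {
    data.frame(pos = as.integer(v$pos), ref = v$ref, alt = v$alt,
               class = v$class, effect = effect,
               codon_pos = codon_pos, aa_ref = aa_ref, aa_alt = aa_alt,
               stringsAsFactors = FALSE)
  }

  if (v$class == "SNP") {
    codon_idx <- off %/% 3L
    codon_pos <- off %% 3L + 1L
    codon <- substr(cds, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
    alt_base <- if (orf$strand == "+") v$alt else revcomp_chr(v$alt)
    mut <- codon
    substr(mut, codon_pos, codon_pos) <- alt_base
    aa0 <- translate_codon(codon); aa1 <- translate_codon(mut)
    eff <- if (aa1 == "*") "stop gained"
           else if (aa0 == aa1) "synonymous coding"
           else "non-synonymous coding"
    return(rec(eff, codon_pos, aa0, aa1))
  }

  ilen <- if (v$class == "deletion") as.integer(v$indel_len %||% 1L)
          else nchar(sub("^\\+", "", v$alt))
  if (ilen %% 3L != 0L) return(rec("frame shift"))

  # rebuild the mutated CDS and look for a premature stop
  if (v$class == "deletion") {
    aligned <- off %% 3L == 0L
    mut_cds <- paste0(substr(cds, 1L, off),
                      substr(cds, off + ilen + 1L, nchar(cds)))
    base_eff <- if (aligned) "codon deletion" else
      "codon change plus codon deletion"
  } else {
    ins_seq <- sub("^\\+", "", v$alt)
    if (orf$strand == "-") ins_seq <- revcomp_chr(ins_seq)
    # insertion sits after coding offset `off` on the coding strand
    cut <- off + 1L
    aligned <- cut %% 3L == 0L
    mut_cds <- paste0(substr(cds, 1L, cut), ins_seq,
                      substr(cds, cut + 1L, nchar(cds)))
    base_eff <- if (aligned) "codon insertion" else
      "codon change plus codon insertion"
  }
  n_cod <- nchar(mut_cds) %/% 3L
  if (n_cod > 0L) {
    aam <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(substr(mut_cds, 1L, 3L * n_cod)),
      no.init.codon = TRUE)))
    if (grepl("*", aam, fixed = TRUE)) return(rec("stop gained"))
  }
  rec(base_eff)
}

orf_cds <- function(orf, sequence) {
  nt <- substr(sequence, orf$start + 1L, orf$end)
  if (orf$strand == "-") nt <- revcomp_chr(nt)
  nt
}

#' Probability that a random single-base codon substitution changes the
#' encoded amino acid
#'
#' The pseudo-SNP neutrality simulation: draw a codon (uniformly over the
#' 61 sense codons of the standard nuclear genetic code, or weighted by a
#' supplied codon usage table), replace one of its three bases with one of
#' the three alternatives at random, and ask whether the encoded amino
#' acid changes. Exact mode enumerates all 9 substitutions of every
#' weighted codon; simulate mode is the Monte-Carlo equivalent and
#' converges to exact as `n` grows. Substitutions creating a stop codon
#' count as amino-acid-changing by default.
#'
#' @param weights named numeric vector of codon weights (e.g. the `count`
#'   or `frequency` column of [compute_codon_usage()]), or NULL for uniform
#'   weights over the 61 sense codons. Weights on stop codons are dropped.
#' @param mode `"exact"` (enumeration) or `"simulate"` (Monte-Carlo).
#' @param n number of simulated pseudo-SNPs in simulate mode.
#' @param seed RNG seed for simulate mode.
#' @param include_stop_gain count stop-gained substitutions as
#'   amino-acid-changing (default TRUE).
#' @return list with `probability`, `mode`, `n` (substitutions enumerated
#'   or simulated), `se` (Monte-Carlo standard error; 0 in exact mode) and
#'   `per_codon` (exact mode: codon, n_synonymous, n_nonsynonymous,
#'   n_stop_gained out of the 9 single-base substitutions).
#' @export
neutral_substitution_probability <- function(weights = NULL,
                                             mode = c("exact", "simulate"),
                                             n = 1e6, seed = 1L,
                                             include_stop_gain = TRUE) {
  mode <- match.arg(mode)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  if (is.null(weights)) weights <- setNames(rep(1, length(sense)), sense)
  weights <- weights[names(weights) %in% sense]
  if (length(weights) == 0L || all(weights == 0))
    input_error("codon weights must include positive weight on sense codons")
  weights <- weights[weights > 0]

  per_codon <- codon_substitution_classes()
  per_codon <- per_codon[per_codon$codon %in% names(weights), , drop = FALSE]
  changing <- per_codon$n_nonsynonymous +
    if (include_stop_gain) per_codon$n_stop_gained else 0L
  p_codon <- changing / 9

  if (mode == "exact") {
    w <- weights[per_codon$codon] / sum(weights)
    return(list(probability = sum(w * p_codon), mode = "exact",
                n = 9L * nrow(per_codon), se = 0, per_codon = per_codon))
  }
  if (n < 1) input_error("n must be >= 1 in simulate mode")
  withr::with_seed(as.integer(seed), {
    cods <- sample(names(weights), n, replace = TRUE,
                   prob = weights / sum(weights))
    pos <- sample.int(3L, n, replace = TRUE)
    old <- substr(cods, pos, pos)
    pick <- sample.int(3L, n, replace = TRUE)
    alt_lut <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                        character(3)))
    alts <- alt_lut[cbind(match(old, DNA_BASES), pick)]
    mut <- cods
    substr(mut, pos, pos) <- alts
    aa0 <- code[cods]; aa1 <- code[mut]
    changed <- if (include_stop_gain) aa1 != aa0
               else aa1 != "*" & aa1 != aa0
    p <- mean(changed)
    list(probability = p, mode = "simulate", n = as.integer(n),
         se = sqrt(p * (1 - p) / n), per_codon = per_codon)
  })
}

# per-codon classification of all 9 single-base substitutions
codon_substitution_classes <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  rows <- lapply(sense, function(cd) {
    syn <- non <- stp <- 0L
    for (p in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cd, p, p))) {
        mut <- cd
        substr(mut, p, p) <- b
        aa <- code[[mut]]
        if (aa == "*") stp <- stp + 1L
        else if (aa == code[[cd]]) syn <- syn + 1L
        else non <- non + 1L
      }
    }
    data.frame(codon = cd, n_synonymous = syn, n_nonsynonymous = non,
               n_stop_gained = stp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Codon-position distribution of in-ORF SNPs
#'
#' @param effects result of [annotate_effects()] (possibly concatenated
#'   over genes).
#' @return named numeric vector of length 3: fraction of in-ORF SNPs at
#'   codon positions 1, 2, 3 (sums to 1). All-NA with a warning when no
#'   in-ORF SNP is present.
#' @export
codon_position_bias <- function(effects) {
  snp <- effects[effects$class == "SNP" & !is.na(effects$codon_pos), ,
                 drop = FALSE]
  if (nrow(snp) == 0L) {
    warning("no in-ORF SNPs; codon-position bias undefined", call. = FALSE)
    return(setNames(rep(NA_real_, 3L), paste0("pos", 1:3)))
  }
  tab <- table(factor(snp$codon_pos, levels = 1:3))
  setNames(as.numeric(tab) / nrow(snp), paste0("pos", 1:3))
}
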
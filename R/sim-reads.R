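#' Simulate short paired-end and long single-end reads from mutated loci
#'
#' Fragments are drawn from isoforms proportionally to their expression
#' weights. Every fragment samples one allele per overlapping mutation site
#' (alternate alleles with probability equal to their allelic fraction, the
#' reference with the remainder), so both mates of a pair carry the same
#' molecule's alleles. Substitution sequencing errors are then added
#' independently per base. Short reads emulate paired 2 x `read_length`
#' sequencing after 5' trimming; long reads are single-end with lengths drawn
#' from `long_read_range` (454-like scale, without flowgram error modelling).
#'
#' @param loci result of [simulate_loci()].
#' @param truth result of [simulate_mutations()] for the same loci.
#' @param config a [sim_config()].
#' @param libraries which libraries to simulate (`"short"`, `"long"`).
#' @return list with `short` (data frame read_id/seq1/seq2), `long`
#'   (read_id/seq), and `origins` (read_id, library, gene_id, isoform_id,
#'   start = 0-based fragment start on the isoform, strand, alleles =
#'   semicolon-joined "pos=alt" records in concatenated-exon coordinates for
#'   non-reference alleles carried by the molecule).
#' @export
simulate_reads <- function(loci, truth, config,
                           libraries = c("short", "long")) {
  validate_sim_config(config)
  libraries <- match.arg(libraries, several.ok = TRUE)
  if ("short" %in% libraries && config$coverage_short <= 0)
    config_error("coverage_short must be > 0 to simulate short reads")
  if ("long" %in% libraries && config$coverage_long <= 0)
    config_error("coverage_long must be > 0 to simulate long reads")

  withr::with_seed(config$seed + 303L, {
    short_rows <- list(); long_rows <- list(); origin_rows <- list()
    for (locus in loci) {
      gid <- locus$gene_id
      len <- truth$gene_lengths[[gid]]
      vars <- truth$variants[truth$variants$gene_id == gid, , drop = FALSE]
      iso_seqs <- vapply(seq_len(nrow(locus$isoforms)), function(i)
        isoform_sequence(locus, i), character(1))
      iso_vars <- lapply(seq_len(nrow(locus$isoforms)), function(i) {
        if (nrow(vars) == 0L) return(vars[0, ])
        v <- vars
        v$iso_pos <- concat_to_isoform_pos(locus, i, v$pos)
        v[!is.na(v$iso_pos), , drop = FALSE]
      })
      w <- locus$isoforms$weight

      if ("short" %in% libraries) {
        n_frag <- max(1L, round(config$coverage_short * len /
                                  (2 * config$read_length)))
        iso_of <- sample.int(length(w), n_frag, replace = TRUE, prob = w)
        for (f in seq_len(n_frag)) {
          i <- iso_of[f]
          res <- draw_fragment(iso_seqs[i], iso_vars[[i]],
                               target_len = rnorm(1, config$fragment_mean,
                                                  config$fragment_sd),
                               min_len = config$read_length)
          rid <- sprintf("%s_sf%04d", gid, f)
          frag <- res$seq
          strand <- if (runif(1) < 0.5) "+" else "-"
          if (strand == "-") frag <- revcomp_chr(frag)
          r1 <- add_seq_errors(substr(frag, 1L, config$read_length),
                               config$error_rate)
          r2 <- add_seq_errors(
            revcomp_chr(substr(frag, nchar(frag) - config$read_length + 1L,
                               nchar(frag))),
            config$error_rate)
          short_rows[[length(short_rows) + 1L]] <-
            data.frame(read_id = rid, seq1 = r1, seq2 = r2,
                       stringsAsFactors = FALSE)
          origin_rows[[length(origin_rows) + 1L]] <-
            data.frame(read_id = rid, library = "short", gene_id = gid,
                       isoform_id = locus$isoforms$isoform_id[i],
                       start = res$start, strand = strand,
                       alleles = res$alleles, stringsAsFactors = FALSE)
        }
      }

      if ("long" %in% libraries) {
        mean_long <- mean(config$long_read_range)
        n_long <- max(1L, round(config$coverage_long * len / mean_long))
        iso_of <- sample.int(length(w), n_long, replace = TRUE, prob = w)
        for (f in seq_len(n_long)) {
          i <- iso_of[f]
          res <- draw_fragment(iso_seqs[i], iso_vars[[i]],
                               target_len = runif(1, config$long_read_range[1],
                                                  config$long_read_range[2]),
                               min_len = min(config$long_read_range[1],
                                             nchar(iso_seqs[i])))
          rid <- sprintf("%s_lr%04d", gid, f)
          frag <- res$seq
          strand <- if (runif(1) < 0.5) "+" else "-"
          if (strand == "-") frag <- revcomp_chr(frag)
          long_rows[[length(long_rows) + 1L]] <-
            data.frame(read_id = rid,
                       seq = add_seq_errors(frag, config$long_error_rate),
                       stringsAsFactors = FALSE)
          origin_rows[[length(origin_rows) + 1L]] <-
            data.frame(read_id = rid, library = "long", gene_id = gid,
                       isoform_id = locus$isoforms$isoform_id[i],
                       start = res$start, strand = strand,
                       alleles = res$alleles, stringsAsFactors = FALSE)
        }
      }
    }
    list(
      short = rbind_or_empty(short_rows,
                             c(read_id = "character", seq1 = "character",
                               seq2 = "character")),
      long = rbind_or_empty(long_rows,
                            c(read_id = "character", seq = "character")),
      origins = rbind_or_empty(origin_rows,
                               c(read_id = "character", library = "character",
                                 gene_id = "character",
                                 isoform_id = "character", start = "integer",
                                 strand = "character", alleles = "character"))
    )
  })
}

rbind_or_empty <- function(rows, proto) {
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  cols <- lapply(proto, function(tp) vector(tp, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# draw one fragment from an isoform, sampling one allele per covered site
draw_fragment <- function(iso_seq, iso_vars, target_len, min_len) {
  iso_len <- nchar(iso_seq)
  flen <- as.integer(max(min_len, min(iso_len, round(target_len))))
  start <- if (iso_len > flen) sample.int(iso_len - flen + 1L, 1L) - 1L else 0L
  frag <- substr(iso_seq, start + 1L, start + flen)
  carried <- character(0)
  if (nrow(iso_vars)) {
    cov <- iso_vars[iso_vars$iso_pos >= start &
                    iso_vars$iso_pos < start + flen, , drop = FALSE]
    if (nrow(cov)) {
      # apply right-to-left so a deletion does not shift later edit positions
      site_order <- unique(cov$site_id[order(cov$iso_pos, decreasing = TRUE)])
      for (sid in site_order) {
        site <- cov[cov$site_id == sid, , drop = FALSE]
        p_ref <- max(0, 1 - sum(site$fraction))
        k <- sample.int(nrow(site) + 1L, 1L,
                        prob = c(site$fraction, p_ref))
        if (k <= nrow(site)) {
          local <- site$iso_pos[k] - start  # 0-based within fragment
          alt <- site$alt[k]
          if (alt == "-") {
            frag <- paste0(substr(frag, 1L, local),
                           substr(frag, local + 2L, nchar(frag)))
          } else {
            substr(frag, local + 1L, local + 1L) <- alt
          }
          carried <- c(carried, sprintf("%d=%s", site$pos[k], alt))
        }
      }
    }
  }
  list(seq = frag, start = start,
       alleles = paste(carried, collapse = ";"))
}

# independent per-base substitution errors
add_seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  seq
}
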
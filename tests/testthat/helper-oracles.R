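# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# plain-R affine-gap Smith-Waterman (score only); gap of length L costs
# open + L * ext
sw_score_oracle <- function(read, ref, match = 1, mismatch = 2,
                            open = 4, ext = 1) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(s)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      d <- H[i - 1, j - 1] + if (r[i - 1] == s[j - 1]) match else -mismatch
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# brute-force six-frame ORF scan by direct codon iteration
orf_bruteforce <- function(sequence, min_aa = 100, require_atg = TRUE) {
  code <- Biostrings::GENETIC_CODE
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  best <- NULL
  for (frame in 1:6) {
    s <- if (frame <= 3) sequence else rc
    off <- (frame - 1) %% 3
    n_codon <- (nchar(s) - off) %/% 3
    if (n_codon < 1) next
    aa <- character(n_codon)
    for (k in seq_len(n_codon))
      aa[k] <- code[[substr(s, off + 3 * k - 2, off + 3 * k)]]
    k <- 1
    while (k <= n_codon) {
      if (!require_atg || aa[k] == "M") {
        # run to the next stop or frame end
        e <- k
        while (e <= n_codon && aa[e] != "*") e <- e + 1
        len <- e - k
        if (len >= min_aa &&
            (is.null(best) || len > best$aa_length)) {
          best <- list(frame = frame, aa_length = len,
                       aa = paste(aa[k:(e - 1)], collapse = ""),
                       nt_start_in_frame = off + 3 * (k - 1))
        }
        k <- e + 1
        next
      }
      k <- k + 1
    }
  }
  best
}

# direct enumeration of the 61 x 9 substitution table
codon_change_oracle <- function(include_stop_gain = TRUE) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  tot <- 0; chg <- 0
  for (cd in sense) for (p in 1:3)
    for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
      mut <- cd
      substr(mut, p, p) <- b
      tot <- tot + 1
      changed <- if (include_stop_gain) code[[mut]] != code[[cd]]
                 else code[[mut]] != "*" && code[[mut]] != code[[cd]]
      if (changed) chg <- chg + 1
    }
  chg / tot
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
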
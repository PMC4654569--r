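#' k-mer abundance spectrum
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement; k must be odd so no k-mer is its own reverse
#' complement) over a set of reads or sequences and returns the abundance
#' histogram: how many distinct k-mers occur 1x, 2x, ... . The spectrum's
#' shape summarizes coverage, heterozygosity and repeat content of the
#' underlying genome.
#'
#' @param sequences character vector of DNA sequences (reads or contigs).
#' @param k odd integer >= 3, no longer than the shortest sequence.
#' @return list of class `clonemut_kmer_spectrum`: `k`, `histogram` (data
#'   frame abundance/n_kmers), `total_kmers` (counted k-mer instances) and
#'   `distinct_kmers`.
#' @export
kmer_spectrum <- function(sequences, k) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L)
    input_error("k must be an odd integer >= 3 (canonicalization requires odd k)")
  sequences <- sequences[nchar(sequences) >= k]
  if (length(sequences) == 0L)
    input_error("no sequence is at least k bases long")
  kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- revcomp_chr(kmers)
  canonical <- ifelse(kmers <= rc, kmers, rc)
  ab <- table(canonical)
  hist <- table(as.integer(ab))
  structure(list(
    k = k,
    histogram = data.frame(abundance = as.integer(names(hist)),
                           n_kmers = as.integer(hist)),
    total_kmers = length(canonical),
    distinct_kmers = length(ab)
  ), class = "clonemut_kmer_spectrum")
}

#' Classify the shape of a k-mer spectrum
#'
#' Smooths the abundance histogram with a moving average, locates the
#' noise boundary (first local minimum after the error-driven peak at
#' abundance 1) and the signal peaks beyond it. No detectable peak -- or no
#' noise boundary at all, the signature of a genome whose per-site allele
#' diversity blurs the spectrum -- classifies as `no-peak`; one peak is
#' `monomodal` (homozygous-like); two peaks whose abundances sit near a 2:1
#' ratio are `bimodal` (heterozygous diploid: the half-coverage peak holds
#' the haplotype-specific k-mers).
#'
#' @param spectrum a [kmer_spectrum()].
#' @param smooth_window moving-average window (abundance bins).
#' @param prominence minimum peak height as a fraction of the largest
#'   smoothed bin beyond the noise boundary.
#' @param ratio_tol tolerance on the 2:1 abundance relation between the two
#'   peaks of a bimodal spectrum (|log2(a_hi/a_lo) - 1| <= ratio_tol).
#' @return list of class `clonemut_spectrum_shape`: `classification`
#'   ("monomodal", "bimodal" or "no-peak"), `peaks` (abundances), and
#'   `noise_boundary` (abundance of the first local minimum, or NA).
#' @export
classify_spectrum <- function(spectrum, smooth_window = 5L,
                              prominence = 0.05, ratio_tol = 0.45) {
  h <- spectrum$histogram
  max_ab <- max(h$abundance)
  y <- numeric(max_ab)
  y[h$abundance] <- h$n_kmers
  sm <- moving_average(y, smooth_window)

  # noise boundary: first local minimum of the smoothed curve; a histogram
  # that rises from abundance 1 has no error/noise limb, so the boundary
  # sits at the origin
  boundary <- NA_integer_
  if (max_ab >= 3L) {
    if (sm[2L] >= sm[1L]) {
      boundary <- 1L
    } else {
      for (i in 2:(max_ab - 1L)) {
        if (sm[i] < sm[i - 1L] && sm[i] <= sm[i + 1L]) {
          boundary <- i
          break
        }
      }
    }
  }
  if (is.na(boundary)) {
    return(structure(list(classification = "no-peak", peaks = integer(0),
                          noise_boundary = NA_integer_),
                     class = "clonemut_spectrum_shape"))
  }
  region <- boundary:max_ab
  thr <- prominence * max(sm[region])
  peaks <- integer(0)
  if (length(region) >= 3L) {
    for (i in region[-c(1L, length(region))]) {
      if (sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L] && sm[i] >= thr)
        peaks <- c(peaks, i)
    }
  }
  # merge plateau neighbours, keep the strongest peaks first
  peaks <- peaks[order(-sm[peaks])]
  keep <- integer(0)
  for (p in peaks)
    if (!length(keep) || all(abs(keep - p) > smooth_window)) keep <- c(keep, p)
  peaks <- sort(keep)

  classification <- if (length(peaks) == 0L) {
    "no-peak"
  } else if (length(peaks) == 1L) {
    "monomodal"
  } else {
    two <- peaks[order(-sm[peaks])][1:2]
    r <- log2(max(two) / min(two))
    if (abs(r - 1) <= ratio_tol) "bimodal" else "monomodal"
  }
  if (classification == "monomodal" && length(peaks) > 1L)
    peaks <- peaks[which.max(sm[peaks])]
  structure(list(classification = classification, peaks = peaks,
                 noise_boundary = boundary),
            class = "clonemut_spectrum_shape"
  )
}

moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  half <- window %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}
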
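#' Extract high-mutation-load and mutation-free gene sets
#'
#' Applies the functional-category filter: from non-transposon genes whose
#' representative sequence is longer than `min_len` bases, the "high" set
#' holds genes with at least `high` PASS SNPs per 1000 bp and the "zero"
#' set holds genes with no PASS SNPs. The two sets are disjoint by
#' construction.
#'
#' @param density per-gene density table ([snp_density()]`$per_gene`).
#' @param annotations data frame with columns gene_id, category,
#'   transposon (logical), length (representative length, bp) and
#'   optionally annotated (logical).
#' @param high density threshold, SNPs per 1000 bp (default 20).
#' @param min_len representative length must exceed this (default 600 bp).
#' @return list with character vectors `high` and `zero`.
#' @export
classify_mutation_load <- function(density, annotations, high = 20,
                                   min_len = 600) {
  shared <- intersect(density$gene_id, annotations$gene_id)
  d <- density[match(shared, density$gene_id), ]
  a <- annotations[match(shared, annotations$gene_id), ]
  eligible <- !a$transposon & a$length > min_len
  list(high = shared[eligible & d$snps_per_kb >= high],
       zero = shared[eligible & d$n_snps == 0L])
}

#' Per-category mutation bias: log2 of high-load vs mutation-free genes
#'
#' For every functional category, counts genes in the high-load and
#' mutation-free sets and reports log2(n_high / n_zero). Categories with
#' only one side populated carry a one-sided flag instead of a ratio (the
#' heat-plot "*" convention); categories with neither are omitted.
#'
#' @param high,zero gene-id vectors from [classify_mutation_load()].
#' @param annotations annotation table (gene_id, category).
#' @return data frame: category, n_high, n_zero, log2_ratio, flag
#'   ("both", "high_only", "zero_only").
#' @export
category_bias <- function(high, zero, annotations) {
  cat_of <- setNames(annotations$category, annotations$gene_id)
  cats <- sort(unique(c(cat_of[high], cat_of[zero])))
  n_high <- as.integer(table(factor(cat_of[high], levels = cats)))
  n_zero <- as.integer(table(factor(cat_of[zero], levels = cats)))
  flag <- ifelse(n_high > 0L & n_zero > 0L, "both",
                 ifelse(n_high > 0L, "high_only", "zero_only"))
  data.frame(category = cats, n_high = n_high, n_zero = n_zero,
             log2_ratio = ifelse(flag == "both", log2(n_high / n_zero),
                                 NA_real_),
             flag = flag, stringsAsFactors = FALSE)
}

#' Thresholded differential expression between two count libraries
#'
#' Normalizes the two libraries on the MA plane (a loess trend of the
#' log-ratio against mean log-count, fitted on genes expressed in both
#' libraries, absorbs library size and intensity-dependent bias), then
#' tests each gene's count split with a two-sided binomial test of
#' `count_a` out of `count_a + count_b` against the normalized expected
#' proportion. The significance flag reproduces the selection chain:
#' minimum count in both libraries, p-value below `alpha`, normalized fold
#' change of at least `fc` (either direction) and, when an `annotated`
#' column is supplied, annotation presence.
#'
#' @param counts data frame with columns gene_id, count_a, count_b and
#'   optionally annotated (logical).
#' @param alpha significance level (default 0.001).
#' @param fc fold-change threshold (default 2).
#' @param min_count minimum raw count in each library (default 10).
#' @param span loess span for the MA trend (default 0.3).
#' @param p_method `"midp"` (default; mid-p two-sided binomial, calibrated
#'   so the null false-positive rate tracks `alpha`) or `"exact"`
#'   (classical exact binomial, conservative under discreteness).
#' @return data frame: gene_id, count_a, count_b, fold_change (normalized
#'   a/b with pseudo-count 0.5), p_value, significant.
#' @export
differential_expression <- function(counts, alpha = 0.001, fc = 2,
                                    min_count = 10L, span = 0.3,
                                    p_method = c("midp", "exact")) {
  p_method <- match.arg(p_method)
  if (any(counts$count_a < 0) || any(counts$count_b < 0))
    input_error("counts must be non-negative")
  tot_a <- sum(counts$count_a); tot_b <- sum(counts$count_b)
  if (tot_a == 0 || tot_b == 0) input_error("library sizes must be > 0")

  a <- counts$count_a; b <- counts$count_b
  m <- log2((a + 0.5) / (b + 0.5))
  av <- 0.5 * (log2(a + 0.5) + log2(b + 0.5))
  both <- a > 0 & b > 0
  trend <- if (sum(both) >= 10L) {
    fit <- loess(m[both] ~ av[both], span = span, degree = 1L,
                 family = "symmetric")
    pr <- rep(NA_real_, length(a))
    pr[both] <- fitted(fit)
    # genes outside the fitted set fall back to the global median offset
    pr[!both] <- stats::median(fitted(fit))
    pr
  } else {
    rep(log2(tot_a / tot_b), length(a))
  }
  ratio <- 2^trend                       # expected a/b under the null
  p_null <- ratio / (1 + ratio)
  n <- a + b

  p_value <- binom_two_sided(a, n, p_null, p_method)
  fold <- (a + 0.5) / ((b + 0.5) * ratio)
  eff_fc <- pmax(fold, 1 / fold)
  significant <- a >= min_count & b >= min_count &
    p_value < alpha & eff_fc >= fc
  if (!is.null(counts$annotated))
    significant <- significant & counts$annotated

  data.frame(gene_id = counts$gene_id, count_a = a, count_b = b,
             fold_change = fold, p_value = p_value,
             significant = significant, stringsAsFactors = FALSE)
}

# vectorized two-sided binomial p-values (mid-p or exact)
binom_two_sided <- function(x, n, p, method) {
  out <- rep(1, length(x))
  pos <- n > 0
  x <- x[pos]; np <- n[pos]; pp <- p[pos]
  d <- dbinom(x, np, pp)
  lo <- pbinom(x - 1, np, pp)         # P(X < x)
  hi <- pbinom(x, np, pp, lower.tail = FALSE)  # P(X > x)
  pv <- if (method == "midp") {
    2 * pmin(lo + 0.5 * d, hi + 0.5 * d)
  } else {
    # classical exact: sum of outcome probabilities <= P(x)
    vapply(seq_along(x), function(i) {
      di <- dbinom(0:np[i], np[i], pp[i])
      sum(di[di <= d[i] * (1 + 1e-7)])
    }, numeric(1))
  }
  out[pos] <- pmin(1, pv)
  out
}
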
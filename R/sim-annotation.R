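#' Simulate a functional-annotation table for simulated genes
#'
#' Assigns each gene a functional-category label (KOG-like), a transposon
#' flag, its representative length and an annotation-presence flag -- the
#' per-gene annotation input the category-bias and differential-expression
#' filters consume. Categories are drawn uniformly; a configurable fraction
#' of genes is flagged as transposon-derived or left unannotated.
#'
#' @param models named list of Reference Gene Models (for lengths), or a
#'   named integer vector of gene lengths.
#' @param categories category labels to draw from.
#' @param p_transposon probability a gene is transposon-flagged.
#' @param p_annotated probability a gene has a homology hit.
#' @param seed RNG seed.
#' @return data frame: gene_id, category, transposon, length, annotated.
#' @export
simulate_annotation <- function(models,
                                categories = paste0("KOG_", LETTERS[1:8]),
                                p_transposon = 0.05, p_annotated = 0.9,
                                seed = 1L) {
  lengths <- if (is.list(models))
    vapply(models, function(m) nchar(m$virtual_sequence), integer(1))
  else models
  withr::with_seed(as.integer(seed) + 404L, {
    data.frame(
      gene_id = names(lengths),
      category = sample(categories, length(lengths), replace = TRUE),
      transposon = runif(length(lengths)) < p_transposon,
      length = as.integer(lengths),
      annotated = runif(length(lengths)) < p_annotated,
      stringsAsFactors = FALSE
    )
  })
}
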
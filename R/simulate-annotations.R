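#' Spike an annotation term with controlled enrichment
#'
#' Assigns a term to genes with probability `baseline_rate` outside the
#' foreground and `odds * baseline_rate` inside it (`odds = 1` gives the
#' null of no enrichment). Used to calibrate the type-I error and power of
#' the Fisher enrichment test.
#'
#' @param genes Character vector of gene ids (the annotation universe).
#' @param term Term id to spike (Pfam or GO syntax).
#' @param foreground Subset of `genes` forming the enriched set.
#' @param odds Probability multiplier inside the foreground (>= 1).
#' @param baseline_rate Probability of carrying the term outside the
#'   foreground.
#' @param seed Integer seed.
#' @return An `annotation_tbl` whose `gene_universe` attribute is `genes`.
#' @export
spike_annotation_enrichment <- function(genes, term, foreground, odds = 1,
                                        baseline_rate = 0.05, seed = NULL) {
  if (!all(foreground %in% genes)) {
    stop_config("foreground must be a subset of genes")
  }
  if (!is.numeric(odds) || odds < 1) stop_config("odds must be >= 1")
  check_fraction(baseline_rate, "baseline_rate")
  p_in <- odds * baseline_rate
  if (p_in > 1) {
    stop_config(sprintf("odds * baseline_rate = %.3g exceeds 1; not a probability", p_in))
  }
  with_seed(seed, {
    p <- ifelse(genes %in% foreground, p_in, baseline_rate)
    hit <- rbinom(length(genes), 1L, p) == 1L
    annotation_table(gene_id = genes[hit],
                     term_id = rep(term, sum(hit)),
                     gene_universe = genes)
  })
}
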
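#' Hypergeometric over-representation tail probability
#'
#' The one-sided enrichment p-value used by [fisher_enrichment()]:
#' `P(X >= k_fg)` for a hypergeometric draw of `n_fg` genes from a
#' background of `n_bg` genes of which `k_bg` carry the term. Vectorized
#' over all four arguments.
#'
#' @param k_fg,k_bg,n_bg,n_fg Nonnegative integer vectors (recycled).
#' @return Numeric vector of upper-tail probabilities.
#' @export
hyper_upper_tail <- function(k_fg, k_bg, n_bg, n_fg) {
  phyper(k_fg - 1, k_bg, n_bg - k_bg, n_fg, lower.tail = FALSE)
}

#' Fisher exact term enrichment
#'
#' Foreground/background over-representation testing of annotation terms.
#' For each term, with `k_bg` annotated genes among the `n_bg` background
#' genes and `k_fg` among the `n_fg` foreground genes, the one-sided
#' p-value is the hypergeometric upper tail `P(X >= k_fg)` (population
#' `n_bg`, successes `k_bg`, draws `n_fg`). P-values are Benjamini-Hochberg
#' adjusted across all tested terms, and a term is flagged enriched when
#' its adjusted p-value is below `alpha` and it has at least `min_fg_hits`
#' foreground genes. Genes without any annotation stay in the denominators.
#'
#' @param foreground Character vector of foreground gene ids (must be a
#'   subset of the background universe unless `auto_restrict = TRUE`).
#' @param annotations An `annotation_tbl` defining terms and the background
#'   universe (attribute `gene_universe`, which includes unannotated genes).
#' @param term_kind `"pfam"` or `"go"`.
#' @param alpha Adjusted-p threshold for the enriched flag.
#' @param universe Optional explicit background gene universe.
#' @param two_sided Use the two-sided Fisher exact p-value instead of the
#'   one-sided over-representation tail.
#' @param min_fg_hits Minimum foreground gene count to call enrichment.
#' @param drop_unannotated Remove genes without any term of `term_kind`
#'   from the universe before testing.
#' @param auto_restrict Drop (with a warning) foreground genes missing from
#'   the universe instead of raising an error.
#' @param descriptions Optional tibble `term_id`, `description`.
#' @return A tibble of class `enrichment_tbl`, sorted by adjusted p-value,
#'   with columns `term_id`, `term_description`, `k_fg`, `n_fg`, `k_bg`,
#'   `n_bg`, `p_value`, `p_adjusted`, `enriched`.
#' @export
fisher_enrichment <- function(foreground, annotations, term_kind = c("pfam", "go"),
                              alpha = 0.05, universe = NULL, two_sided = FALSE,
                              min_fg_hits = 2L, drop_unannotated = FALSE,
                              auto_restrict = FALSE, descriptions = NULL) {
  term_kind <- match.arg(term_kind)
  ann <- annotations |> filter(.data$kind == term_kind)
  universe <- universe %||% attr(annotations, "gene_universe") %||% unique(annotations$gene_id)
  universe <- unique(universe)
  if (drop_unannotated) universe <- intersect(universe, unique(ann$gene_id))
  foreground <- unique(foreground)
  missing_fg <- setdiff(foreground, universe)
  if (length(missing_fg)) {
    if (auto_restrict) {
      warn(sprintf("dropping %d foreground gene(s) absent from the background universe",
                   length(missing_fg)))
      foreground <- intersect(foreground, universe)
    } else {
      stop_validate(paste0("foreground gene(s) absent from the background universe: ",
                           paste(head(missing_fg, 5L), collapse = ", ")))
    }
  }
  n_bg <- length(universe)
  n_fg <- length(foreground)
  ann <- ann |> filter(.data$gene_id %in% universe) |> distinct(.data$gene_id, .data$term_id)
  counts <- ann |>
    group_by(.data$term_id) |>
    summarise(k_bg = n(), k_fg = sum(.data$gene_id %in% foreground), .groups = "drop")
  if (nrow(counts) == 0L) {
    out <- tibble(term_id = character(), term_description = character(),
                  k_fg = integer(), n_fg = integer(), k_bg = integer(),
                  n_bg = integer(), p_value = numeric(), p_adjusted = numeric(),
                  enriched = logical())
    class(out) <- c("enrichment_tbl", class(tibble()))
    return(out)
  }
  counts$n_fg <- n_fg
  counts$n_bg <- n_bg
  if (two_sided) {
    counts$p_value <- map_dbl(seq_len(nrow(counts)), function(i) {
      with(counts[i, ], fisher.test(matrix(c(k_fg, n_fg - k_fg,
                                             k_bg - k_fg, n_bg - n_fg - (k_bg - k_fg)),
                                           nrow = 2L))$p.value)
    })
  } else {
    counts$p_value <- hyper_upper_tail(counts$k_fg, counts$k_bg,
                                       counts$n_bg, counts$n_fg)
  }
  counts$p_adjusted <- p.adjust(counts$p_value, method = "BH")
  counts$enriched <- counts$p_adjusted < alpha & counts$k_fg >= min_fg_hits
  if (!is.null(descriptions)) {
    counts <- counts |> left_join(descriptions, by = "term_id") |>
      rename(term_description = "description")
  } else {
    counts$term_description <- NA_character_
  }
  out <- counts |>
    select("term_id", "term_description", "k_fg", "n_fg", "k_bg", "n_bg",
           "p_value", "p_adjusted", "enriched") |>
    arrange(.data$p_adjusted, .data$p_value, .data$term_id)
  class(out) <- c("enrichment_tbl", class(tibble()))
  out
}
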
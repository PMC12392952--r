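# Leucine-rich-repeat receptor-like kinase (LRR-RLK) identification cascade
# over precomputed domain-hit tables, subfamily assignment by nearest
# reference, and pan-set / duplication summaries.

#' The 20 LRR-RLK subfamily labels
#'
#' Nineteen described subfamilies (I-XV, with the VI, VIII, X and XIII
#' splits) plus the unclassified catch-all subfamily LRR-XVI.
#' @export
LRR_SUBFAMILIES <- c("LRR-I", "LRR-II", "LRR-III", "LRR-IV", "LRR-V",
                     "LRR-VI-1", "LRR-VI-2", "LRR-VII", "LRR-VIII-1",
                     "LRR-VIII-2", "LRR-IX", "LRR-Xa", "LRR-Xb", "LRR-XI",
                     "LRR-XII", "LRR-XIIIa", "LRR-XIIIb", "LRR-XIV",
                     "LRR-XV", "LRR-XVI")

# The eight LRR profile accessions plus the kinase profile.
LRR_PFAM_PROFILES <- c("PF00560", "PF07723", "PF07725", "PF12799",
                       "PF13306", "PF13516", "PF13855")
KINASE_PFAM <- "PF00069"

#' Identify LRR-RLK candidate proteins
#'
#' A protein qualifies as an LRR-RLK when it has at least one passing
#' protein-kinase domain hit, at least one passing LRR domain hit, and at
#' least one transmembrane segment; proteins without a TM segment are
#' excluded. Acceptance is monotone: adding passing hits never disqualifies
#' a protein.
#'
#' @param domain_hits A `domain_hit_tbl` (see [read_domain_hits()]).
#' @param lrr_profiles Pfam accessions accepted as LRR evidence (used to
#'   cross-check `LRR`-class rows that carry a Pfam id).
#' @return A tibble of class `lrr_rlk_tbl`: `protein_id`, `has_kinase`,
#'   `n_lrr`, `n_tm` — one row per qualifying protein.
#' @export
classify_lrr_rlk <- function(domain_hits, lrr_profiles = LRR_PFAM_PROFILES) {
  passing <- domain_hits |> filter(.data$passes_cutoff)
  lrr_ok <- passing$domain_class == "LRR" &
    (passing$domain_id == "" | passing$domain_id %in% lrr_profiles)
  counts <- passing |>
    mutate(is_lrr = lrr_ok) |>
    group_by(.data$protein_id) |>
    summarise(has_kinase = any(.data$domain_class == "KINASE"),
              n_lrr = sum(.data$is_lrr),
              n_tm = sum(.data$domain_class == "TM"), .groups = "drop")
  out <- counts |>
    filter(.data$has_kinase, .data$n_lrr >= 1L, .data$n_tm >= 1L)
  class(out) <- c("lrr_rlk_tbl", class(tibble()))
  out
}

#' Assign LRR-RLK subfamilies by nearest reference
#'
#' Each candidate is assigned the subfamily of its nearest reference
#' protein, provided the distance does not exceed `max_distance`;
#' otherwise (or when no distance is available) it falls into the
#' unclassified subfamily `LRR-XVI`. Exact distance ties are broken
#' deterministically by reference id order.
#'
#' @param candidates An `lrr_rlk_tbl` (or tibble with `protein_id`).
#' @param reference_distances Tibble `protein_id`, `reference_id`,
#'   `distance` (substitutions/site to each reference panel member).
#' @param reference_subfamilies Tibble `reference_id`, `subfamily` (labels
#'   among the 19 described subfamilies).
#' @param max_distance Maximum distance for a confident assignment
#'   (default 1.0 substitutions/site).
#' @return `candidates` with a `subfamily` factor column over the 20
#'   labels.
#' @export
assign_subfamily <- function(candidates, reference_distances,
                             reference_subfamilies, max_distance = 1.0) {
  if (nrow(reference_subfamilies) == 0L) {
    stop_config("reference panel is empty")
  }
  bad <- setdiff(unique(reference_subfamilies$subfamily), LRR_SUBFAMILIES)
  if (length(bad)) {
    stop_config(paste0("unknown subfamily label(s): ", paste(bad, collapse = ", ")))
  }
  nearest <- reference_distances |>
    inner_join(reference_subfamilies, by = "reference_id") |>
    group_by(.data$protein_id) |>
    arrange(.data$distance, .data$reference_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    mutate(assigned = ifelse(.data$distance <= max_distance,
                             .data$subfamily, "LRR-XVI")) |>
    select("protein_id", "assigned")
  out <- candidates |>
    left_join(nearest, by = "protein_id") |>
    mutate(subfamily = factor(.data$assigned %|% "LRR-XVI",
                              levels = LRR_SUBFAMILIES)) |>
    select(-"assigned")
  class(out) <- c(setdiff(class(candidates), class(tibble())), class(tibble()))
  out
}

#' Summarise an LRR-RLKome
#'
#' @param records An `lrr_rlk_tbl` with `subfamily` assignments.
#' @param proteins Tibble `protein_id`, `genome_id` locating every protein.
#' @param genome_totals Tibble `genome_id`, `n_genes` (total genes per
#'   genome, denominator of the per-genome percentage).
#' @param gene_classes Optional tibble `gene_id`, `pan_class` (protein ids
#'   doubling as gene ids).
#' @param duplication_labels Optional `duplication_tbl`.
#' @return A list: `by_genome` (count and percentage of genome gene
#'   total; attribute `mean_per_genome`, integer-rounded), `by_subfamily`,
#'   `by_pan_set` (with `share_pct` of the LRR-RLKome, 2 dp), and
#'   `duplication` (WGD/TD counts and shares).
#' @export
summarize_lrr_rlkome <- function(records, proteins, genome_totals = NULL,
                                 gene_classes = NULL, duplication_labels = NULL) {
  located <- records |> left_join(proteins, by = "protein_id")
  by_genome <- located |>
    count(.data$genome_id, name = "n_lrr_rlk")
  if (!is.null(genome_totals)) {
    by_genome <- by_genome |>
      left_join(genome_totals, by = "genome_id") |>
      mutate(pct_of_genome = round(100 * .data$n_lrr_rlk / .data$n_genes, 4L))
  }
  attr(by_genome, "mean_per_genome") <- round(mean(by_genome$n_lrr_rlk))
  by_subfamily <- records |> count(.data$subfamily, .drop = FALSE, name = "n_genes")
  by_pan_set <- NULL
  if (!is.null(gene_classes)) {
    by_pan_set <- records |>
      left_join(gene_classes |> select(protein_id = 1L, pan_class = 2L),
                by = "protein_id") |>
      count(.data$pan_class, name = "n_genes") |>
      mutate(share_pct = round(100 * .data$n_genes / sum(.data$n_genes), 2L))
  }
  duplication <- NULL
  if (!is.null(duplication_labels)) {
    duplication <- records |>
      left_join(duplication_labels |> select(protein_id = 1L, label = "label"),
                by = "protein_id") |>
      count(.data$label, name = "n_genes") |>
      mutate(share_pct = round(100 * .data$n_genes / sum(.data$n_genes), 2L))
  }
  list(by_genome = by_genome, by_subfamily = by_subfamily,
       by_pan_set = by_pan_set, duplication = duplication)
}

#' LRR-RLKome shares from printed totals
#'
#' Arithmetic helper: given the total LRR-RLK pan-gene count, the core,
#' whole-genome-duplicate and tandem-duplicate member counts and the number
#' of genomes, reports the core/WGD/TD percentage shares (2 dp) and the
#' integer-rounded mean gene count per genome.
#'
#' @param n_total,n_core,n_wgd,n_td Counts.
#' @param n_genomes Number of genomes.
#' @return One-row tibble `core_pct`, `wgd_pct`, `td_pct`,
#'   `mean_per_genome`.
#' @export
lrr_share_summary <- function(n_total, n_core, n_wgd, n_td, n_genomes) {
  tibble(core_pct = round(100 * n_core / n_total, 2L),
         wgd_pct = round(100 * n_wgd / n_total, 2L),
         td_pct = round(100 * n_td / n_total, 2L),
         mean_per_genome = round(n_total / n_genomes))
}
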
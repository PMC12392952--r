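#' Build an orthogroup-by-genome occupancy table
#'
#' Counts, for every orthogroup and genome, the number of genes that genome
#' contributes to the group. The total over all entries equals the total
#' gene count of the input.
#'
#' @param orthogroups An `orthogroup_tbl` (long tibble `group_id`,
#'   `genome_id`, `gene_id`).
#' @param genome_ids Optional character vector fixing the genome collection;
#'   defaults to the collection attached to `orthogroups`.
#' @return A tidy tibble of class `pan_occupancy` with columns `group_id`,
#'   `genome_id`, `n_genes` (absent combinations have zero genes) and
#'   attribute `genome_ids`.
#' @export
build_occupancy <- function(orthogroups, genome_ids = NULL) {
  if (nrow(orthogroups) == 0L) stop_validate("orthogroup table is empty")
  genome_ids <- genome_ids %||% orthogroup_genomes(orthogroups)
  out <- orthogroups |>
    count(.data$group_id, .data$genome_id, name = "n_genes")
  attr(out, "genome_ids") <- genome_ids
  class(out) <- c("pan_occupancy", class(tibble()))
  out
}

#' Dense occupancy count matrix
#'
#' @param occupancy A `pan_occupancy`.
#' @return An integer matrix (orthogroups x genomes) of gene counts.
#' @export
occupancy_matrix <- function(occupancy) {
  genome_ids <- attr(occupancy, "genome_ids") %||% sort(unique(occupancy$genome_id))
  groups <- sort(unique(occupancy$group_id))
  M <- matrix(0L, length(groups), length(genome_ids),
              dimnames = list(groups, genome_ids))
  M[cbind(match(occupancy$group_id, groups),
          match(occupancy$genome_id, genome_ids))] <- as.integer(occupancy$n_genes)
  M
}

#' Pan-gene set classification thresholds
#'
#' @param softcore_fraction Fraction of genomes above which a non-core group
#'   is softcore (default 0.99; a group present in at least
#'   `round(softcore_fraction * N)` but fewer than `N` genomes is softcore).
#' @param private_max_genomes Maximum number of genomes for a private group
#'   (default 1).
#' @return A list of class `pan_class_thresholds`.
#' @export
pan_class_thresholds <- function(softcore_fraction = 0.99, private_max_genomes = 1L) {
  check_fraction(softcore_fraction, "softcore_fraction", open_lower = TRUE, open_upper = TRUE)
  private_max_genomes <- check_count(private_max_genomes, "private_max_genomes", min = 1L)
  structure(list(softcore_fraction = softcore_fraction,
                 private_max_genomes = private_max_genomes),
            class = "pan_class_thresholds")
}

#' Classify orthogroups into pan-gene sets
#'
#' Partitions orthogroups into the four pan-gene sets by presence count `k`
#' out of `N` genomes: core (`k = N`), private
#' (`k <= private_max_genomes`), softcore
#' (`round(softcore_fraction * N) <= k < N`) and dispensable (everything
#' else). The partition is total and exclusive. When the softcore threshold
#' rounds to `N` or more, a warning is raised and the softcore set is empty.
#'
#' @param occupancy A `pan_occupancy` (needs `N >= 2` genomes).
#' @param thresholds A [pan_class_thresholds()].
#' @return A tibble of class `pan_classification` with columns `group_id`,
#'   `presence_count`, `n_genes` and `pan_class` (factor core/softcore/
#'   dispensable/private); attributes `n_genomes` and `thresholds`.
#' @export
classify_pangene_sets <- function(occupancy, thresholds = pan_class_thresholds()) {
  genome_ids <- attr(occupancy, "genome_ids") %||% unique(occupancy$genome_id)
  N <- length(genome_ids)
  if (N < 2L) stop_validate("classification needs at least 2 genomes")
  soft_min <- round(thresholds$softcore_fraction * N)
  if (soft_min >= N) {
    warn(sprintf("softcore threshold round(%g * %d) = %d leaves no softcore range",
                 thresholds$softcore_fraction, N, soft_min))
  }
  pm <- thresholds$private_max_genomes
  out <- occupancy |>
    filter(.data$n_genes > 0L) |>
    group_by(.data$group_id) |>
    summarise(presence_count = n(), n_genes = sum(.data$n_genes), .groups = "drop") |>
    mutate(pan_class = factor(dplyr::case_when(
      .data$presence_count == N ~ "core",
      .data$presence_count <= pm ~ "private",
      .data$presence_count >= soft_min ~ "softcore",
      TRUE ~ "dispensable"
    ), levels = PAN_CLASSES))
  attr(out, "n_genomes") <- N
  attr(out, "thresholds") <- thresholds
  class(out) <- c("pan_classification", class(tibble()))
  out
}

#' Summarise a pan-gene classification
#'
#' @param classification A `pan_classification`.
#' @return Tibble with per-class orthogroup counts, gene totals, and shares
#'   (`share_pct`, rounded to 1 decimal place, of the orthogroup total).
#' @export
pan_class_summary <- function(classification) {
  classification |>
    group_by(.data$pan_class, .drop = FALSE) |>
    summarise(n_groups = n(), total_genes = sum(.data$n_genes), .groups = "drop") |>
    mutate(share_pct = round(100 * .data$n_groups / sum(.data$n_groups), 1L))
}

#' Pan-gene set composition from class counts
#'
#' Arithmetic helper reproducing reported composition figures from per-class
#' orthogroup counts alone: the total and each class's percentage share at
#' one decimal place.
#'
#' @param n_groups Named numeric vector of per-class orthogroup counts
#'   (names among core/softcore/dispensable/private).
#' @return Tibble with columns `pan_class`, `n_groups`, `share_pct`, plus
#'   attribute `total`.
#' @examples
#' pan_set_composition(c(core = 12843, softcore = 3735,
#'                       dispensable = 28790, private = 13698))
#' @export
pan_set_composition <- function(n_groups) {
  if (is.null(names(n_groups)) || !all(names(n_groups) %in% PAN_CLASSES)) {
    stop_config("n_groups must be named with pan-gene classes")
  }
  total <- sum(n_groups)
  out <- tibble(pan_class = factor(names(n_groups), levels = PAN_CLASSES),
                n_groups = unname(n_groups),
                share_pct = round(100 * unname(n_groups) / total, 1L))
  attr(out, "total") <- total
  out
}
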
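#' Taxon-group-specific orthogroups
#'
#' An orthogroup is specific to a taxon group when it is present in at
#' least `min_group_genomes` genomes of that group and absent from every
#' genome outside it. Core-class orthogroups are excluded from the tested
#' universe before evaluation (they are present everywhere by definition);
#' set `include_core = TRUE` for exploratory use.
#'
#' @param occupancy A `pan_occupancy`.
#' @param genomes Genome table covering every genome of the occupancy.
#' @param classes Optional `pan_classification` used to exclude core
#'   groups; computed from `occupancy` when `NULL`.
#' @param min_group_genomes Minimum number of focal-group genomes carrying
#'   the group (default 1).
#' @param include_core Keep core-class groups in the tested universe.
#' @return A tibble with columns `taxon_group`, `group_id`, `n_genomes`
#'   (presence within the focal group) and `n_genes` (genes harboured).
#'   Specific sets of different groups are disjoint by construction.
#' @export
group_specific_orthogroups <- function(occupancy, genomes, classes = NULL,
                                       min_group_genomes = 1L,
                                       include_core = FALSE) {
  check_genome_table(genomes)
  genome_ids <- attr(occupancy, "genome_ids") %||% unique(occupancy$genome_id)
  unassigned <- setdiff(genome_ids, genomes$genome_id)
  if (length(unassigned)) {
    stop_config(paste0("genome(s) without taxon group assignment: ",
                       paste(unassigned, collapse = ", ")))
  }
  if (!include_core) {
    classes <- classes %||% classify_pangene_sets(occupancy)
    core_ids <- classes$group_id[classes$pan_class == "core"]
  } else {
    core_ids <- character()
  }
  present <- occupancy |>
    filter(.data$n_genes > 0L, !(.data$group_id %in% core_ids)) |>
    left_join(genomes |> select("genome_id", "taxon_group"), by = "genome_id")
  per_group <- present |>
    group_by(.data$group_id) |>
    summarise(n_taxa = dplyr::n_distinct(.data$taxon_group),
              taxon_group = .data$taxon_group[1L],
              n_genomes = n(),
              n_genes = sum(.data$n_genes), .groups = "drop")
  per_group |>
    filter(.data$n_taxa == 1L, .data$n_genomes >= min_group_genomes) |>
    select("taxon_group", "group_id", "n_genomes", "n_genes") |>
    arrange(.data$taxon_group, .data$group_id)
}

#' Taxon-group-specific annotation terms
#'
#' A term (typically a Pfam id) is specific to a taxon group when it is
#' attached to at least one gene in that group's genomes and to no gene in
#' any other group's genomes. Unannotated genes are ignored.
#'
#' @param annotations An `annotation_tbl`.
#' @param genes Tibble mapping `gene_id` to `genome_id` (an
#'   `orthogroup_tbl` or gene-record table works).
#' @param genomes Genome table with taxon groups.
#' @param kind Term kind to test (default `"pfam"`).
#' @return Tibble `taxon_group`, `term_id`, `n_genes`.
#' @export
specific_pfam_ids <- function(annotations, genes, genomes, kind = "pfam") {
  check_genome_table(genomes)
  ann <- annotations |> filter(.data$kind == !!kind)
  if (nrow(ann) == 0L) {
    return(tibble(taxon_group = factor(character(), levels = TAXON_GROUPS),
                  term_id = character(), n_genes = integer()))
  }
  gene_map <- genes |> distinct(.data$gene_id, .data$genome_id) |>
    left_join(genomes |> select("genome_id", "taxon_group"), by = "genome_id")
  ann |>
    inner_join(gene_map, by = "gene_id") |>
    group_by(.data$term_id) |>
    summarise(n_taxa = dplyr::n_distinct(.data$taxon_group),
              taxon_group = .data$taxon_group[1L],
              n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    filter(.data$n_taxa == 1L) |>
    select("taxon_group", "term_id", "n_genes") |>
    arrange(.data$taxon_group, .data$term_id)
}

#' Per-genome presence/copy-number report for target orthogroups
#'
#' @param occupancy A `pan_occupancy`.
#' @param target_groups Orthogroup ids to report.
#' @param genomes Genome table.
#' @return A tidy tibble of class `pav_report` (`group_id`, `genome_id`,
#'   `taxon_group`, `n_genes`, `present`) covering every target x genome
#'   combination, zeros included.
#' @export
gene_pav_report <- function(occupancy, target_groups, genomes) {
  check_genome_table(genomes)
  known <- unique(occupancy$group_id)
  bad <- setdiff(target_groups, known)
  if (length(bad)) {
    stop_lookup(paste0("unknown orthogroup id(s): ", paste(bad, collapse = ", ")))
  }
  genome_ids <- attr(occupancy, "genome_ids") %||% unique(occupancy$genome_id)
  grid <- tidyr::expand_grid(group_id = target_groups, genome_id = genome_ids)
  out <- grid |>
    left_join(as_tibble(occupancy), by = c("group_id", "genome_id")) |>
    mutate(n_genes = as.integer(.data$n_genes %|% 0L), present = .data$n_genes > 0L) |>
    left_join(genomes |> select("genome_id", "taxon_group"), by = "genome_id") |>
    select("group_id", "genome_id", "taxon_group", "n_genes", "present")
  class(out) <- c("pav_report", class(tibble()))
  out
}

#' Write/read a PAV report
#' @param report A `pav_report`.
#' @param path TSV path.
#' @return `path` / the re-read `pav_report`.
#' @export
write_pav_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pav_report
#' @export
read_pav_report <- function(path) {
  out <- strip_readr_attrs(readr::read_tsv(path, col_types = "cccil",
                                           progress = FALSE))
  out$taxon_group <- factor(out$taxon_group, levels = TAXON_GROUPS)
  class(out) <- c("pav_report", class(tibble()))
  out
}
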
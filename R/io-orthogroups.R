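#' Read an OrthoFinder-style orthogroup table
#'
#' Reads the tab-separated `Orthogroups.tsv` dialect (first column the
#' orthogroup id, one column per genome, genes within a cell joined by
#' `", "`), optionally merges the companion unassigned-genes table in which
#' every gene becomes a singleton orthogroup, and returns the merged table in
#' tidy long form.
#'
#' @param assigned_path Path to the assigned-orthogroups TSV.
#' @param unassigned_path Optional path to the unassigned-genes TSV; every
#'   gene in it becomes its own singleton orthogroup.
#' @param genomes Genome table from [genome_table()]; its `genome_id` values
#'   must cover every genome column in the files.
#' @param sep Separator joining genes within a cell (default `", "`).
#'
#' @return A tibble of class `orthogroup_tbl` with columns `group_id`,
#'   `genome_id`, `gene_id` (one row per gene) and attribute `genome_ids`
#'   holding the full genome collection (genomes with no gene in a group
#'   simply have no row).
#' @export
read_orthogroups <- function(assigned_path, unassigned_path = NULL, genomes, sep = ", ") {
  check_genome_table(genomes)
  assigned <- parse_orthogroup_file(assigned_path, genomes, sep)
  if (!is.null(unassigned_path)) {
    un <- parse_orthogroup_file(unassigned_path, genomes, sep)
    # every unassigned gene becomes a singleton orthogroup
    un <- un |>
      group_by(.data$group_id) |>
      mutate(group_id = if (n() == 1L) .data$group_id
             else paste0(.data$group_id, "_", seq_len(n()))) |>
      ungroup()
    clash <- intersect(unique(assigned$group_id), unique(un$group_id))
    if (length(clash)) {
      stop_parse(paste0("orthogroup ids present in both files: ",
                        paste(head(clash, 5L), collapse = ", ")))
    }
    assigned <- bind_rows(assigned, un)
  }
  dup <- assigned$gene_id[duplicated(assigned$gene_id)]
  if (length(dup)) {
    stop_validate(paste0("gene(s) assigned to more than one orthogroup: ",
                         paste(unique(head(dup, 5L)), collapse = ", ")))
  }
  as_orthogroup_tbl(assigned, genome_ids = genomes$genome_id)
}

parse_orthogroup_file <- function(path, genomes, sep) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop_parse(sprintf("'%s': expected an orthogroup column plus genome columns", path))
  genome_cols <- names(raw)[-1L]
  unknown <- setdiff(genome_cols, genomes$genome_id)
  if (length(unknown)) {
    stop_config(paste0("'", path, "': genome column(s) not in genome table: ",
                       paste(unknown, collapse = ", ")))
  }
  bad_rows <- which(is.na(raw[[1L]]) | raw[[1L]] == "")
  if (length(bad_rows)) {
    stop_parse(sprintf("'%s': missing orthogroup id at line %d", path, bad_rows[1L] + 1L))
  }
  names(raw)[1L] <- "group_id"
  long <- raw |>
    pivot_longer(-"group_id", names_to = "genome_id", values_to = "genes") |>
    filter(!is.na(.data$genes), .data$genes != "")
  long |>
    mutate(gene_id = str_split(.data$genes, stringr::fixed(sep))) |>
    select("group_id", "genome_id", "gene_id") |>
    unnest("gene_id") |>
    mutate(gene_id = str_trim(.data$gene_id)) |>
    filter(.data$gene_id != "")
}

as_orthogroup_tbl <- function(x, genome_ids) {
  out <- as_tibble(x[c("group_id", "genome_id", "gene_id")])
  attr(out, "genome_ids") <- genome_ids
  class(out) <- c("orthogroup_tbl", class(tibble()))
  out
}

orthogroup_genomes <- function(orthogroups) {
  attr(orthogroups, "genome_ids") %||% sort(unique(orthogroups$genome_id))
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' Inverse of [read_orthogroups()]: genes of one genome within a group are
#' joined by `sep`, groups are rows sorted by id, genomes are columns.
#'
#' @param orthogroups An `orthogroup_tbl`.
#' @param path Output TSV path.
#' @param sep Within-cell gene separator.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path, sep = ", ") {
  genome_ids <- orthogroup_genomes(orthogroups)
  wide <- orthogroups |>
    group_by(.data$group_id, .data$genome_id) |>
    summarise(genes = paste(.data$gene_id, collapse = sep), .groups = "drop") |>
    pivot_wider(names_from = "genome_id", values_from = "genes") |>
    arrange(.data$group_id)
  missing_cols <- setdiff(genome_ids, names(wide))
  for (g in missing_cols) wide[[g]] <- NA_character_
  wide <- wide[c("group_id", genome_ids)]
  names(wide)[1L] <- "Orthogroup"
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}
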
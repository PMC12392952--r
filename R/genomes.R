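#' Build a genome collection table
#'
#' A genome collection records, for every genome in the pangenome, its
#' identifier, the taxon group it belongs to (distant wild relatives `WILD`,
#' ancestral `SP`, early-domesticated `SLC`, or cultivated `SLL`) and an
#' optional display name. Most analyses that compare taxon groups take this
#' table alongside orthogroup data.
#'
#' @param genome_id Character vector of unique genome identifiers.
#' @param taxon_group Character vector (recycled if length 1) with values in
#'   `c("WILD", "SP", "SLC", "SLL")`.
#' @param display_name Optional character vector of human-readable names;
#'   defaults to `genome_id`.
#'
#' @return A tibble with columns `genome_id`, `taxon_group` (factor with the
#'   four levels) and `display_name`.
#' @examples
#' genome_table(c("LA0716", "EA00371"), c("WILD", "SLL"))
#' @export
genome_table <- function(genome_id, taxon_group, display_name = genome_id) {
  genome_id <- as.character(genome_id)
  if (anyDuplicated(genome_id)) {
    stop_validate(paste0("duplicated genome_id: ",
                         paste(unique(genome_id[duplicated(genome_id)]), collapse = ", ")))
  }
  if (length(taxon_group) == 1L) taxon_group <- rep(taxon_group, length(genome_id))
  bad <- setdiff(unique(taxon_group), TAXON_GROUPS)
  if (length(bad)) {
    stop_config(paste0("unknown taxon_group: ", paste(bad, collapse = ", "),
                       " (expected one of ", paste(TAXON_GROUPS, collapse = ", "), ")"))
  }
  tibble(
    genome_id = genome_id,
    taxon_group = factor(taxon_group, levels = TAXON_GROUPS),
    display_name = as.character(display_name)
  )
}

check_genome_table <- function(genomes, arg = "genomes") {
  if (!is.data.frame(genomes) || !all(c("genome_id", "taxon_group") %in% names(genomes))) {
    stop_config(sprintf("`%s` must be a genome table with genome_id and taxon_group columns", arg))
  }
  if (anyNA(genomes$taxon_group)) {
    stop_config("every genome must carry a taxon_group assignment")
  }
  invisible(genomes)
}
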
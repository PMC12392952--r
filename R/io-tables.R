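#' Read a per-gene functional annotation table
#'
#' The expected layout is a headered TSV with columns `gene_id`, `pfam_ids`
#' (";"-joined Pfam accessions, may be empty) and `go_ids` (";"-joined GO
#' term ids, may be empty), as extracted from InterProScan-style output.
#' Term ids are validated syntactically (`PF` + 5 digits, `GO:` + 7 digits).
#'
#' @param tsv_path Path to the TSV.
#' @return A tidy tibble of class `annotation_tbl` with columns `gene_id`,
#'   `term_id`, `kind` (`"pfam"` or `"go"`). The attribute `gene_universe`
#'   records every gene seen in the file, including genes without any term,
#'   so enrichment denominators can include unannotated genes.
#' @export
read_annotations <- function(tsv_path) {
  raw <- readr::read_tsv(tsv_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(as_annotation_tbl(tibble(gene_id = character(), term_id = character(),
                                    kind = character()), character()))
  }
  if (ncol(raw) < 3L) stop_parse(sprintf("'%s': expected columns gene_id, pfam_ids, go_ids", tsv_path))
  names(raw)[1:3] <- c("gene_id", "pfam_ids", "go_ids")
  split_terms <- function(x) {
    out <- str_split(ifelse(is.na(x), "", x), stringr::fixed(";"))
    lapply(out, function(v) str_trim(v[v != ""]))
  }
  long <- bind_rows(
    tibble(gene_id = raw$gene_id, term_id = split_terms(raw$pfam_ids), kind = "pfam"),
    tibble(gene_id = raw$gene_id, term_id = split_terms(raw$go_ids), kind = "go")
  ) |> unnest("term_id")
  validate_term_ids(long$term_id, long$kind)
  as_annotation_tbl(long, unique(raw$gene_id))
}

validate_term_ids <- function(term_id, kind) {
  ok <- ifelse(kind == "pfam",
               str_detect(term_id, "^PF\\d{5}$"),
               str_detect(term_id, "^GO:\\d{7}$"))
  if (any(!ok)) {
    stop_parse(paste0("invalid term id(s): ",
                      paste(head(unique(term_id[!ok]), 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

as_annotation_tbl <- function(x, gene_universe) {
  out <- as_tibble(x[c("gene_id", "term_id", "kind")])
  attr(out, "gene_universe") <- gene_universe
  class(out) <- c("annotation_tbl", class(tibble()))
  out
}

#' Construct an annotation table from tidy data
#'
#' @param gene_id,term_id Character vectors of equal length.
#' @param kind `"pfam"` or `"go"` per row (recycled if length 1); inferred
#'   from the term id syntax when `NULL`.
#' @param gene_universe All genes of the annotation universe; defaults to the
#'   genes present in `gene_id`.
#' @return An `annotation_tbl`.
#' @export
annotation_table <- function(gene_id, term_id, kind = NULL, gene_universe = NULL) {
  if (is.null(kind)) {
    kind <- ifelse(str_detect(term_id, "^GO:"), "go", "pfam")
  }
  if (length(kind) == 1L) kind <- rep(kind, length(gene_id))
  validate_term_ids(term_id, kind)
  as_annotation_tbl(tibble(gene_id = as.character(gene_id),
                           term_id = as.character(term_id), kind = kind),
                    gene_universe %||% unique(as.character(gene_id)))
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]; genes of the universe without terms are
#' written with empty term columns.
#'
#' @param annotations An `annotation_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  universe <- attr(annotations, "gene_universe") %||% unique(annotations$gene_id)
  join <- function(k) {
    annotations |>
      filter(.data$kind == k) |>
      group_by(.data$gene_id) |>
      summarise(ids = paste(sort(.data$term_id), collapse = ";"), .groups = "drop")
  }
  out <- tibble(gene_id = sort(universe)) |>
    left_join(join("pfam") |> rename(pfam_ids = "ids"), by = "gene_id") |>
    left_join(join("go") |> rename(go_ids = "ids"), by = "gene_id") |>
    mutate(pfam_ids = .data$pfam_ids %|% "", go_ids = .data$go_ids %|% "")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

`%|%` <- function(x, y) ifelse(is.na(x), y, x)

DOMAIN_CLASSES <- c("KINASE", "LRR", "TM", "OTHER")

#' Read a domain-hit table
#'
#' Headered TSV with columns `protein_id`, `domain_id`, `domain_class`
#' (`KINASE`, `LRR`, `TM`, `OTHER`), `start`, `end`, `passes_cutoff`
#' (`TRUE`/`FALSE`). `KINASE` rows must carry the protein-kinase profile
#' accession `PF00069`; `TM` rows (transmembrane segments) carry no Pfam id.
#'
#' @param tsv_path Path to the TSV.
#' @return A tibble of class `domain_hit_tbl`.
#' @export
read_domain_hits <- function(tsv_path) {
  raw <- strip_readr_attrs(readr::read_tsv(tsv_path, col_types = "ccciil",
                                           progress = FALSE))
  if (nrow(raw) == 0L) {
    raw <- tibble(protein_id = character(), domain_id = character(),
                  domain_class = character(), start = integer(), end = integer(),
                  passes_cutoff = logical())
  }
  names(raw) <- c("protein_id", "domain_id", "domain_class", "start", "end", "passes_cutoff")
  raw$domain_id <- raw$domain_id %|% ""
  validate_domain_hits(raw)
  class(raw) <- c("domain_hit_tbl", class(tibble()))
  raw
}

validate_domain_hits <- function(hits) {
  bad <- setdiff(unique(hits$domain_class), DOMAIN_CLASSES)
  if (length(bad)) stop_parse(paste0("unknown domain_class: ", paste(bad, collapse = ", ")))
  if (any(hits$end < hits$start)) stop_validate("domain hit with end < start")
  k <- hits$domain_class == "KINASE" & hits$domain_id != "PF00069"
  if (any(k)) stop_validate("KINASE hits must carry the PF00069 profile")
  tm <- hits$domain_class == "TM" & str_detect(hits$domain_id, "^PF")
  if (any(tm)) stop_validate("TM rows must not carry a Pfam id")
  invisible(hits)
}

#' Write a domain-hit table
#' @param hits A `domain_hit_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping sequences as a named character
#' vector, the in-memory representation used throughout the package.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write newick trees
#'
#' Wrappers over [ape::read.tree()] / [ape::write.tree()].
#'
#' @param path Newick file path.
#' @return `read_newick()`: an `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
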
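#' Read gene coordinates from a GFF3 file
#'
#' Imports `gene` features from a GFF3 file and returns one record per gene
#' with a 0-based `rank` along each sequence region, recomputed from the
#' coordinates: genes are ordered by ascending start, ties broken by
#' lexicographic `gene_id`. The rank, not the base-pair coordinate, is what
#' the adjacency and collinearity analyses consume.
#'
#' @param gff3_path Path to a GFF3 file containing `gene` features with an
#'   `ID` attribute.
#' @param genome_id Genome identifier attached to every record.
#'
#' @return A tibble with columns `gene_id`, `genome_id`, `seq_region`,
#'   `start`, `end` (1-based inclusive), `strand` and `rank`.
#' @export
read_gene_coordinates <- function(gff3_path, genome_id) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(add_gene_ranks(tibble(gene_id = character(), genome_id = character(),
                                 seq_region = character(), start = integer(),
                                 end = integer(), strand = character())))
  }
  ids <- as.character(gr$ID)
  if (length(ids) != length(gr) || anyNA(ids) || any(ids == "")) {
    stop_parse(sprintf("'%s': gene feature without ID attribute", gff3_path))
  }
  genes <- tibble(
    gene_id = ids,
    genome_id = genome_id,
    seq_region = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  genes$strand[genes$strand == "*"] <- "."
  validate_gene_records(genes)
  add_gene_ranks(genes)
}

validate_gene_records <- function(genes) {
  bad <- which(genes$end < genes$start)
  if (length(bad)) {
    stop_validate(sprintf("gene '%s': end (%d) < start (%d)",
                          genes$gene_id[bad[1L]], genes$end[bad[1L]], genes$start[bad[1L]]))
  }
  dup <- genes |> count(.data$genome_id, .data$gene_id) |> filter(n > 1L)
  if (nrow(dup)) {
    stop_validate(paste0("duplicated gene_id within genome: ",
                         paste(head(dup$gene_id, 5L), collapse = ", ")))
  }
  invisible(genes)
}

#' Recompute gene ranks along each sequence region
#'
#' Ranks are a 0-based contiguous run per (genome, seq_region), assigned by
#' ascending start coordinate with ties broken by lexicographic gene id, so
#' they are invariant to the input row order.
#'
#' @param genes A gene-record tibble (`gene_id`, `genome_id`, `seq_region`,
#'   `start`, `end`, `strand`).
#' @return The same tibble with a recomputed `rank` column, sorted by
#'   genome, region and rank.
#' @export
add_gene_ranks <- function(genes) {
  genes |>
    arrange(.data$genome_id, .data$seq_region, .data$start, .data$gene_id) |>
    group_by(.data$genome_id, .data$seq_region) |>
    mutate(rank = seq_len(n()) - 1L) |>
    ungroup()
}

#' Write gene records as a minimal GFF3 file
#'
#' @param genes Gene-record tibble.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_coordinates <- function(genes, path, source = "panortho") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$seq_region, source, genes$start, genes$end,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
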
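# Single-copy ortholog supermatrix construction and a desk-scale
# neighbor-joining tree with bootstrap support.

#' Extract single-copy orthogroups
#'
#' Orthogroups with exactly one gene in every listed genome (including any
#' outgroup genomes), the input to supermatrix phylogeny.
#'
#' @param orthogroups An `orthogroup_tbl`.
#' @param genome_ids Genomes that must each contribute exactly one gene;
#'   defaults to the table's genome collection.
#' @return Character vector of orthogroup ids.
#' @export
extract_single_copy <- function(orthogroups, genome_ids = NULL) {
  genome_ids <- genome_ids %||% orthogroup_genomes(orthogroups)
  counts <- orthogroups |>
    filter(.data$genome_id %in% genome_ids) |>
    count(.data$group_id, .data$genome_id)
  counts |>
    group_by(.data$group_id) |>
    summarise(ok = n() == length(genome_ids) && all(.data$n == 1L), .groups = "drop") |>
    filter(.data$ok) |>
    pull(.data$group_id)
}

#' Conserved-block filter configuration
#'
#' @param min_block_length Minimum run length of kept columns (default 5).
#' @param max_gap_fraction Maximum fraction of sequences gapped in a kept
#'   column (default 0.5, gaps allowed in up to half the sequences).
#' @param min_conserved_fraction Minimum frequency of the modal residue in
#'   a kept column (default 0.5).
#' @return A list of class `block_filter_config`.
#' @export
block_filter_config <- function(min_block_length = 5L, max_gap_fraction = 0.5,
                                min_conserved_fraction = 0.5) {
  min_block_length <- check_count(min_block_length, "min_block_length", min = 1L)
  check_fraction(max_gap_fraction, "max_gap_fraction")
  check_fraction(min_conserved_fraction, "min_conserved_fraction", open_lower = TRUE)
  structure(list(min_block_length = min_block_length,
                 max_gap_fraction = max_gap_fraction,
                 min_conserved_fraction = min_conserved_fraction),
            class = "block_filter_config")
}

#' Filter an alignment to conserved blocks
#'
#' A column is a candidate when its gap fraction is at most
#' `max_gap_fraction` and its most frequent (non-gap) residue reaches
#' `min_conserved_fraction` of the sequences; maximal runs of candidate
#' columns shorter than `min_block_length` are dropped. Filtering is
#' idempotent.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences.
#' @param config A [block_filter_config()].
#' @return A list of class `filtered_alignment` with `alignment` (filtered
#'   sequences) and `kept` (strictly increasing source column indices).
#' @export
filter_conserved_blocks <- function(alignment, config = block_filter_config()) {
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop_validate("aligned sequences must have equal length")
  M <- do.call(rbind, strsplit(alignment, ""))
  n_seq <- nrow(M)
  gap_frac <- colMeans(M == "-")
  modal_frac <- apply(M, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    max(table(res)) / n_seq
  })
  candidate <- gap_frac <= config$max_gap_fraction &
    modal_frac >= config$min_conserved_fraction
  keep <- logical(length(candidate))
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= config$min_block_length) {
      keep[starts[i]:ends[i]] <- TRUE
    }
  }
  kept <- which(keep)
  filtered <- apply(M[, kept, drop = FALSE], 1L, paste, collapse = "")
  structure(list(alignment = setNames(filtered, names(alignment)), kept = kept),
            class = "filtered_alignment")
}

#' Concatenate per-orthogroup alignments into a supermatrix
#'
#' @param alignments Named list of alignments (named character vectors);
#'   each must cover every genome exactly once.
#' @param genome_order Optional genome ordering for the output.
#' @return A list of class `supermatrix` with `alignment` (per-genome
#'   concatenated sequences) and `partitions` (tibble `orthogroup`,
#'   `start`, `end`, 1-based inclusive columns).
#' @export
concatenate_alignments <- function(alignments, genome_order = NULL) {
  if (!length(alignments)) stop_validate("no alignments to concatenate")
  if (is.null(names(alignments))) names(alignments) <- paste0("aln", seq_along(alignments))
  genomes <- genome_order %||% sort(names(alignments[[1L]]))
  for (nm in names(alignments)) {
    miss <- setdiff(genomes, names(alignments[[nm]]))
    if (length(miss)) {
      stop_validate(sprintf("alignment '%s' missing genome(s): %s",
                            nm, paste(miss, collapse = ", ")))
    }
  }
  lens <- vapply(alignments, function(a) unique(nchar(a[genomes]))[1L], numeric(1L))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- vapply(genomes, function(g) {
    paste(vapply(alignments, function(a) a[[g]], character(1L)), collapse = "")
  }, character(1L))
  structure(list(alignment = setNames(seqs, genomes),
                 partitions = tibble(orthogroup = names(alignments),
                                     start = as.integer(starts),
                                     end = as.integer(ends))),
            class = "supermatrix")
}

# pairwise p-distance over sites where both sequences are ungapped
p_distance_matrix <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- M[i, ] != "-" & M[j, ] != "-"
      D[i, j] <- D[j, i] <- if (any(ok)) mean(M[i, ok] != M[j, ok]) else NA_real_
    }
  }
  D
}

nj_from_matrix <- function(M) {
  D <- p_distance_matrix(M)
  if (nrow(M) == 3L) {
    # three taxa: single unresolved topology, branch lengths by the
    # three-point formula
    d <- D
    x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    txt <- sprintf("(%s:%f,%s:%f,%s:%f);", rownames(M)[1], x,
                   rownames(M)[2], y, rownames(M)[3], z)
    return(ape::read.tree(text = txt))
  }
  ape::nj(as.dist(D))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds a neighbor-joining tree from pairwise p-distances of the
#' supermatrix (protein or nucleotide characters; sites where either
#' sequence is gapped are excluded pairwise) and assigns bipartition
#' support as the fraction of site-resampling bootstrap replicates
#' containing each internal branch. With three sequences the single
#' unresolved topology is returned.
#'
#' @param supermatrix A `supermatrix` or named character vector of aligned
#'   sequences (>= 3).
#' @param n_bootstrap Bootstrap replicates (0 skips support values).
#' @param seed Integer seed for resampling.
#' @param outgroup Optional tip label(s) to root on.
#' @return An `ape::phylo`; `node.label` holds support fractions when
#'   bootstrapping was requested.
#' @export
nj_tree <- function(supermatrix, n_bootstrap = 100L, seed = NULL, outgroup = NULL) {
  aln <- if (inherits(supermatrix, "supermatrix")) supermatrix$alignment else supermatrix
  if (length(aln) < 3L) stop_validate("need at least 3 sequences")
  M <- do.call(rbind, strsplit(aln, ""))
  rownames(M) <- names(aln)
  main <- nj_from_matrix(M)
  root_it <- function(tr) {
    if (is.null(outgroup)) return(tr)
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  if (n_bootstrap > 0L && length(aln) > 3L) {
    boots <- with_seed(seed, {
      lapply(seq_len(n_bootstrap), function(b) {
        cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
        nj_from_matrix(M[, cols, drop = FALSE])
      })
    })
    counts <- ape::prop.clades(main, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    main$node.label <- counts / n_bootstrap
  }
  root_it(main)
}
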
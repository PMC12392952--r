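# Duplication-origin classification: tandem arrays from rank adjacency of
# co-orthogroup genes, whole-genome duplicates from collinear blocks against
# an outgroup genome that lacks the recent polyploidy.

#' Find tandem duplication arrays
#'
#' Maximal runs of genes of one genome that share an orthogroup (paralogs)
#' and sit at consecutive ranks on one sequence region; with `max_gap = g`,
#' consecutive members may be separated by up to `g` intervening genes.
#' Every array has at least two members.
#'
#' @param genes Ranked gene records (see [add_gene_ranks()]).
#' @param orthogroups An `orthogroup_tbl` (defines paralogy via
#'   co-membership within one genome).
#' @param max_gap Maximum number of intervening genes (default 0, strict
#'   adjacency).
#' @return A tibble of class `tandem_tbl`: `array_id`, `genome_id`,
#'   `seq_region`, `group_id`, `gene_id`, `rank`.
#' @export
find_tandem_arrays <- function(genes, orthogroups, max_gap = 0L) {
  max_gap <- check_count(max_gap, "max_gap")
  joined <- genes |>
    inner_join(orthogroups |> select("gene_id", "genome_id", "group_id"),
               by = c("gene_id", "genome_id"))
  runs <- joined |>
    group_by(.data$genome_id, .data$seq_region, .data$group_id) |>
    filter(n() >= 2L) |>
    arrange(.data$rank, .by_group = TRUE) |>
    mutate(new_run = c(0L, as.integer(diff(.data$rank) > max_gap + 1L)),
           run = cumsum(.data$new_run)) |>
    group_by(.data$run, .add = TRUE) |>
    filter(n() >= 2L) |>
    ungroup()
  if (nrow(runs) == 0L) {
    out <- tibble(array_id = character(), genome_id = character(),
                  seq_region = character(), group_id = character(),
                  gene_id = character(), rank = integer())
  } else {
    out <- runs |>
      mutate(array_key = paste(.data$genome_id, .data$seq_region,
                               .data$group_id, .data$run, sep = "|")) |>
      mutate(array_id = sprintf("TA%04d", match(.data$array_key, unique(.data$array_key)))) |>
      select("array_id", "genome_id", "seq_region", "group_id", "gene_id", "rank") |>
      arrange(.data$array_id, .data$rank)
  }
  class(out) <- c("tandem_tbl", class(tibble()))
  out
}

#' Cross-genome anchor pairs from shared orthogroups
#'
#' Anchors for collinearity analysis: pairs of genes, one per genome, that
#' belong to the same orthogroup, annotated with the rank coordinates of
#' both sides. This replaces raw BLAST hit pairs; a user-supplied anchor
#' table with the same columns can be passed to
#' [chain_collinear_blocks()] directly.
#'
#' @param orthogroups An `orthogroup_tbl`.
#' @param genes Ranked gene records for both genomes.
#' @param genome_a,genome_b The two genomes (a = focal, b = outgroup).
#' @return Tibble `group_id`, `gene_a`, `region_a`, `rank_a`, `gene_b`,
#'   `region_b`, `rank_b`.
#' @export
orthogroup_anchors <- function(orthogroups, genes, genome_a, genome_b) {
  side <- function(gid, suffix) {
    orthogroups |>
      filter(.data$genome_id == gid) |>
      inner_join(genes |> select("gene_id", "seq_region", "rank"), by = "gene_id") |>
      select("group_id", "gene_id", "seq_region", "rank") |>
      rlang::set_names(c("group_id", paste0(c("gene_", "region_", "rank_"), suffix)))
  }
  inner_join(side(genome_a, "a"), side(genome_b, "b"),
             by = "group_id", relationship = "many-to-many")
}

# Longest strictly-monotone chain (increasing side A; side B strictly
# increasing or decreasing per `direction`), with per-step rank gaps bounded
# on both sides. O(n^2) dynamic programme over anchors sorted by rank_a.
longest_chain <- function(ra, rb, direction, max_rank_gap) {
  n <- length(ra)
  ord <- order(ra, if (direction > 0) rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  best_len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- ra[j] < ra[i] && (ra[i] - ra[j]) <= max_rank_gap + 1L &&
        (if (direction > 0) rb[j] < rb[i] && (rb[i] - rb[j]) <= max_rank_gap + 1L
         else rb[j] > rb[i] && (rb[j] - rb[i]) <= max_rank_gap + 1L)
      if (ok && best_len[j] + 1L > best_len[i]) {
        best_len[i] <- best_len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best_len)
  chain <- integer(best_len[end])
  k <- best_len[end]
  while (!is.na(end)) {
    chain[k] <- end
    k <- k - 1L
    end <- prev[end]
  }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Greedy extraction of collinear blocks per region pair: repeatedly find
#' the longest chain of anchors with strictly monotone ranks on both sides
#' (same or inverted orientation) and per-step rank gaps of at most
#' `max_rank_gap`, record it if it has at least `min_block` anchors, remove
#' its anchors, and repeat. Each anchor belongs to at most one block.
#'
#' @param anchors Anchor tibble from [orthogroup_anchors()] (or equivalent).
#' @param min_block Minimum anchors per block (default 15).
#' @param max_rank_gap Maximum intervening ranks between consecutive
#'   anchors on either side (default 25).
#' @return A tibble of class `collinear_tbl`: `block_id`, `region_a`,
#'   `a_lo`, `a_hi`, `region_b`, `b_lo`, `b_hi`, `n_anchors`,
#'   `orientation`, and a list-column `anchor_rows` with the member anchor
#'   rows.
#' @export
chain_collinear_blocks <- function(anchors, min_block = 15L, max_rank_gap = 25L) {
  min_block <- check_count(min_block, "min_block", min = 2L)
  max_rank_gap <- check_count(max_rank_gap, "max_rank_gap")
  blocks <- list()
  if (nrow(anchors)) {
    pairs <- anchors |> distinct(.data$region_a, .data$region_b)
    for (p in seq_len(nrow(pairs))) {
      sub <- anchors |>
        filter(.data$region_a == pairs$region_a[p], .data$region_b == pairs$region_b[p])
      repeat {
        if (nrow(sub) < min_block) break
        up <- longest_chain(sub$rank_a, sub$rank_b, +1L, max_rank_gap)
        down <- longest_chain(sub$rank_a, sub$rank_b, -1L, max_rank_gap)
        take <- if (length(up) >= length(down)) up else down
        orientation <- if (length(up) >= length(down)) "same" else "inverted"
        if (length(take) < min_block) break
        members <- sub[take, ]
        blocks[[length(blocks) + 1L]] <- tibble(
          region_a = pairs$region_a[p],
          a_lo = min(members$rank_a), a_hi = max(members$rank_a),
          region_b = pairs$region_b[p],
          b_lo = min(members$rank_b), b_hi = max(members$rank_b),
          n_anchors = nrow(members),
          orientation = orientation,
          anchor_rows = list(members)
        )
        sub <- sub[-take, ]
      }
    }
  }
  out <- if (length(blocks)) {
    list_rbind(blocks) |>
      arrange(desc(.data$n_anchors)) |>
      mutate(block_id = sprintf("CB%04d", seq_len(n())), .before = 1L)
  } else {
    tibble(block_id = character(), region_a = character(), a_lo = integer(),
           a_hi = integer(), region_b = character(), b_lo = integer(),
           b_hi = integer(), n_anchors = integer(), orientation = character(),
           anchor_rows = list())
  }
  class(out) <- c("collinear_tbl", class(tibble()))
  out
}

#' Classify gene duplication origin
#'
#' Labels every gene of the focal genome as `WGD`, `TD` or `other`. A gene
#' is a whole-genome duplicate when it lies within the focal-side rank
#' interval of at least two collinear blocks whose outgroup-side intervals
#' overlap (two focal regions anchored to one outgroup region) and it
#' shares an orthogroup with a gene in the sister region. Tandem-array
#' members are labelled `TD`; `TD` takes precedence over `WGD` when both
#' apply. The remainder is `other`.
#'
#' @param genes Ranked gene records (all genomes; the focal genome's genes
#'   are labelled).
#' @param orthogroups An `orthogroup_tbl`.
#' @param blocks Collinear blocks of the focal genome against the outgroup
#'   ([chain_collinear_blocks()] on focal-vs-outgroup anchors).
#' @param tandem_arrays Output of [find_tandem_arrays()].
#' @param target_genome Focal genome id.
#' @return A tibble of class `duplication_tbl`: `gene_id`, `genome_id`,
#'   `label` (factor WGD/TD/other), `evidence`.
#' @export
classify_duplicates <- function(genes, orthogroups, blocks, tandem_arrays,
                                target_genome) {
  tg <- genes |> filter(.data$genome_id == target_genome)
  if (nrow(tg) == 0L) stop_validate(sprintf("no genes for genome '%s'", target_genome))
  if (anyNA(tg$rank)) stop_validate("genes must carry ranks; run add_gene_ranks()")
  gene_group <- orthogroups |>
    filter(.data$genome_id == target_genome) |>
    select("gene_id", "group_id")
  tg <- tg |> left_join(gene_group, by = "gene_id")

  wgd <- character()
  evidence <- list()
  if (nrow(blocks) >= 2L) {
    genes_in_block <- function(b) {
      tg |> filter(.data$seq_region == blocks$region_a[b],
                   .data$rank >= blocks$a_lo[b], .data$rank <= blocks$a_hi[b])
    }
    combos <- combn(seq_len(nrow(blocks)), 2L)
    for (k in seq_len(ncol(combos))) {
      b1 <- combos[1L, k]; b2 <- combos[2L, k]
      if (blocks$region_b[b1] != blocks$region_b[b2]) next
      overlap <- blocks$b_lo[b1] <= blocks$b_hi[b2] && blocks$b_lo[b2] <= blocks$b_hi[b1]
      if (!overlap) next
      same_span <- blocks$region_a[b1] == blocks$region_a[b2] &&
        blocks$a_lo[b1] == blocks$a_lo[b2] && blocks$a_hi[b1] == blocks$a_hi[b2]
      if (same_span) next
      g1 <- genes_in_block(b1)
      g2 <- genes_in_block(b2)
      hit1 <- g1$gene_id[g1$group_id %in% g2$group_id & !is.na(g1$group_id)]
      hit2 <- g2$gene_id[g2$group_id %in% g1$group_id & !is.na(g2$group_id)]
      hits <- c(hit1, hit2)
      if (length(hits)) {
        wgd <- c(wgd, hits)
        evidence[[paste(blocks$block_id[b1], blocks$block_id[b2], sep = "+")]] <- hits
      }
    }
  }
  wgd <- unique(wgd)
  td <- tandem_arrays |>
    filter(.data$genome_id == target_genome) |>
    select("gene_id", "array_id")
  ev_map <- tibble(gene_id = as.character(unlist(evidence, use.names = FALSE)),
                   evidence = as.character(rep(names(evidence), lengths(evidence)))) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  out <- tg |>
    select("gene_id", "genome_id") |>
    mutate(label = factor(dplyr::case_when(
      .data$gene_id %in% td$gene_id ~ "TD",
      .data$gene_id %in% wgd ~ "WGD",
      TRUE ~ "other"
    ), levels = c("WGD", "TD", "other"))) |>
    left_join(bind_rows(ev_map, td |> rename(evidence = "array_id")) |>
                distinct(.data$gene_id, .keep_all = TRUE), by = "gene_id")
  class(out) <- c("duplication_tbl", class(tibble()))
  out
}

#' Summarise duplication labels
#'
#' Per-genome, per-pan-gene-set and per-taxon-group counts of whole-genome
#' and tandem duplicates, with percentages of the respective totals at two
#' decimal places.
#'
#' @param labels A `duplication_tbl` (possibly covering several genomes).
#' @param gene_classes Optional tibble `gene_id`, `pan_class` for the
#'   per-set table.
#' @param genomes Optional genome table for the per-taxon-group table.
#' @return A list of tibbles: `by_genome`, `by_pan_set` (NULL without
#'   `gene_classes`), `by_taxon_group` (NULL without `genomes`).
#' @export
summarize_duplication <- function(labels, gene_classes = NULL, genomes = NULL) {
  count_block <- function(df, key) {
    df |>
      group_by(dplyr::across(dplyr::all_of(key))) |>
      summarise(total_genes = n(),
                wgd_genes = sum(.data$label == "WGD"),
                td_genes = sum(.data$label == "TD"), .groups = "drop") |>
      mutate(wgd_pct = ifelse(.data$total_genes > 0,
                              round(100 * .data$wgd_genes / .data$total_genes, 2L), 0),
             td_pct = ifelse(.data$total_genes > 0,
                             round(100 * .data$td_genes / .data$total_genes, 2L), 0))
  }
  by_genome <- count_block(labels, "genome_id")
  by_pan_set <- NULL
  if (!is.null(gene_classes)) {
    by_pan_set <- labels |>
      left_join(gene_classes |> select(gene_id = 1L, pan_class = 2L), by = "gene_id") |>
      count_block("pan_class") |>
      rename(gene_set = "pan_class")
  }
  by_taxon_group <- NULL
  if (!is.null(genomes)) {
    by_taxon_group <- labels |>
      left_join(genomes |> select("genome_id", "taxon_group"), by = "genome_id") |>
      count_block("taxon_group")
  }
  list(by_genome = by_genome, by_pan_set = by_pan_set,
       by_taxon_group = by_taxon_group)
}

#' Duplication percentages from printed counts
#'
#' Arithmetic helper reproducing summary-table percentages (two decimal
#' places) from total, whole-genome-duplicate and tandem-duplicate gene
#' counts.
#'
#' @param gene_set Character vector of set labels.
#' @param total_genes,wgd_genes,td_genes Numeric count vectors.
#' @return Tibble in summary-table layout with `wgd_pct` and `td_pct`.
#' @export
duplication_rate_table <- function(gene_set, total_genes, wgd_genes, td_genes) {
  tibble(gene_set = gene_set, total_genes = total_genes,
         wgd_genes = wgd_genes,
         wgd_pct = round(100 * wgd_genes / total_genes, 2L),
         td_genes = td_genes,
         td_pct = round(100 * td_genes / total_genes, 2L))
}
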
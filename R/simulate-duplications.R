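#' Implant tandem arrays and whole-genome-duplication blocks
#'
#' Edits a simulated pangenome so that known duplication signal exists for
#' recovery testing. Tandem arrays are created by adding extra gene copies
#' of a target-genome gene immediately downstream of it (same orthogroup,
#' consecutive ranks). Whole-genome-duplication blocks are created by
#' copying a run of consecutive single-copy anchor orthogroups (single-copy
#' in both the target genome and the outgroup) onto a fresh contig of the
#' target genome, producing two collinear target-side runs anchored to the
#' same outgroup region. Truth labels for every target-genome gene are
#' returned for sensitivity/false-positive assessment.
#'
#' @param sim Output of [simulate_pangenome()] (list with `genes`,
#'   `orthogroups`, `genomes`).
#' @param target_genome Genome receiving the implants (default: first
#'   genome that is not the outgroup).
#' @param outgroup_id Genome used as the collinearity outgroup; must carry
#'   single-copy anchors.
#' @param n_tandem_arrays Number of tandem arrays to implant.
#' @param tandem_sizes Integer vector of candidate array sizes (>= 2),
#'   sampled per array.
#' @param n_wgd_blocks Number of duplicated blocks to implant.
#' @param block_length Anchor orthogroups per block.
#' @param seed Integer seed.
#' @return A list with updated `genes` and `orthogroups`, the original
#'   `genomes`, and `truth_labels` (tibble `gene_id`, `genome_id`, `truth`
#'   in `WGD`/`TD`/`other` covering every target-genome gene).
#' @export
implant_duplications <- function(sim, target_genome = NULL, outgroup_id,
                                 n_tandem_arrays = 0L, tandem_sizes = 2:3,
                                 n_wgd_blocks = 0L, block_length = 20L,
                                 seed = 1L) {
  genes <- sim$genes
  orthogroups <- sim$orthogroups
  genome_ids <- orthogroup_genomes(orthogroups)
  if (!outgroup_id %in% genome_ids) {
    stop_config(sprintf("outgroup '%s' is not in the genome collection", outgroup_id))
  }
  target_genome <- target_genome %||% setdiff(genome_ids, outgroup_id)[1L]
  n_tandem_arrays <- check_count(n_tandem_arrays, "n_tandem_arrays")
  n_wgd_blocks <- check_count(n_wgd_blocks, "n_wgd_blocks")
  block_length <- check_count(block_length, "block_length", min = 2L)
  if (any(tandem_sizes < 2L)) stop_config("tandem_sizes must be >= 2")

  copy_counts <- orthogroups |>
    count(.data$group_id, .data$genome_id)
  single_in <- function(gid) {
    copy_counts |> filter(.data$genome_id == gid, .data$n == 1L) |> pull(.data$group_id)
  }
  anchors <- intersect(single_in(target_genome), single_in(outgroup_id))
  target_genes <- genes |> filter(.data$genome_id == target_genome)
  out_genes <- genes |> filter(.data$genome_id == outgroup_id)

  with_seed(seed, {
    new_genes <- list()
    new_og <- list()
    td_genes <- character()
    wgd_genes <- character()
    gene2group <- orthogroups |>
      filter(.data$genome_id == target_genome) |>
      select("gene_id", "group_id")

    # --- WGD blocks: runs of consecutive anchors on the outgroup contig ---
    if (n_wgd_blocks > 0L) {
      anchor_out <- out_genes |>
        inner_join(orthogroups |> filter(.data$genome_id == outgroup_id) |>
                     select("gene_id", "group_id"), by = "gene_id") |>
        filter(.data$group_id %in% anchors) |>
        arrange(.data$seq_region, .data$rank)
      runs <- list()
      i <- 1L
      while (i + block_length - 1L <= nrow(anchor_out) && length(runs) < n_wgd_blocks) {
        seg <- anchor_out[i:(i + block_length - 1L), ]
        if (length(unique(seg$seq_region)) == 1L) {
          runs[[length(runs) + 1L]] <- seg$group_id
          i <- i + block_length + 2L   # leave a spacer between blocks
        } else {
          i <- i + 1L
        }
      }
      if (length(runs) < n_wgd_blocks) {
        stop_config(sprintf("outgroup contig too short: only %d anchor run(s) of length %d available",
                            length(runs), block_length))
      }
      for (b in seq_along(runs)) {
        run_groups <- runs[[b]]
        originals <- gene2group |> filter(.data$group_id %in% run_groups)
        contig <- sprintf("wgd_block_%d", b)
        copies <- tibble(
          gene_id = sprintf("%s_wgd%02d_%02d", target_genome, b, seq_along(run_groups)),
          genome_id = target_genome,
          seq_region = contig,
          start = 1000L * (seq_along(run_groups) - 1L) + 1L,
          end = 1000L * (seq_along(run_groups) - 1L) + 501L,
          strand = "+"
        )
        new_genes[[length(new_genes) + 1L]] <- copies
        new_og[[length(new_og) + 1L]] <- tibble(group_id = run_groups,
                                                genome_id = target_genome,
                                                gene_id = copies$gene_id)
        wgd_genes <- c(wgd_genes, originals$gene_id, copies$gene_id)
      }
    }

    # --- tandem arrays: extra adjacent copies of single-copy target genes ---
    if (n_tandem_arrays > 0L) {
      used <- unique(c(wgd_genes))
      used_groups <- gene2group |> filter(.data$gene_id %in% used) |> pull(.data$group_id)
      candidates <- target_genes |>
        inner_join(gene2group, by = "gene_id") |>
        filter(.data$group_id %in% setdiff(anchors, used_groups))
      if (nrow(candidates) < n_tandem_arrays) {
        stop_config("not enough single-copy genes to host the requested tandem arrays")
      }
      hosts <- candidates[sort(sample.int(nrow(candidates), n_tandem_arrays)), ]
      sizes <- tandem_sizes[sample.int(length(tandem_sizes), n_tandem_arrays, replace = TRUE)]
      for (a in seq_len(n_tandem_arrays)) {
        host <- hosts[a, ]
        k <- sizes[a] - 1L
        copies <- tibble(
          gene_id = sprintf("%s_td%02d_%02d", target_genome, a, seq_len(k)),
          genome_id = target_genome,
          seq_region = host$seq_region,
          start = host$start + 500L + 10L * seq_len(k),
          end = host$start + 505L + 10L * seq_len(k),
          strand = "+"
        )
        new_genes[[length(new_genes) + 1L]] <- copies
        new_og[[length(new_og) + 1L]] <- tibble(group_id = host$group_id,
                                                genome_id = target_genome,
                                                gene_id = copies$gene_id)
        td_genes <- c(td_genes, host$gene_id, copies$gene_id)
      }
    }

    genes_out <- bind_rows(genes, list_rbind(new_genes)) |> add_gene_ranks()
    og_out <- as_orthogroup_tbl(
      bind_rows(as_tibble(orthogroups), list_rbind(new_og)),
      genome_ids = genome_ids
    )
    truth <- genes_out |>
      filter(.data$genome_id == target_genome) |>
      transmute(.data$gene_id, .data$genome_id,
                truth = factor(dplyr::case_when(
                  .data$gene_id %in% td_genes ~ "TD",
                  .data$gene_id %in% wgd_genes ~ "WGD",
                  TRUE ~ "other"
                ), levels = c("WGD", "TD", "other")))
    list(genes = genes_out, orthogroups = og_out, genomes = sim$genomes,
         truth_labels = truth, target_genome = target_genome,
         outgroup_id = outgroup_id)
  })
}
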
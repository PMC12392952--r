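#' Configuration for pangenome simulation
#'
#' Encodes the study conditions the generator emulates: the number of
#' genomes and their split over the four taxon groups, the target pan-gene
#' class proportions, the number of orthogroups and the mean gene copy
#' number per present genome. Defaults reproduce a 61-genome collection
#' (13 distant wild relatives, 11 SP, 12 SLC, 25 SLL) with class
#' proportions taken from the reported composition of the tomato
#' super-pangenome (core 12843, softcore 3735, dispensable 28790, private
#' 13698 of 59066 orthogroups).
#'
#' @param n_genomes Total number of genomes.
#' @param group_sizes Named integer vector over `WILD`, `SP`, `SLC`, `SLL`
#'   summing to `n_genomes`.
#' @param class_proportions Named fractions over core/softcore/dispensable/
#'   private summing to 1 (tolerance 1e-9).
#' @param n_orthogroups Number of orthogroups to generate.
#' @param mean_copies Mean gene copies per present genome (geometric,
#'   minimum 1).
#' @param softcore_fraction,private_max_genomes Classifier thresholds the
#'   generated occupancies must satisfy (match
#'   [pan_class_thresholds()] defaults).
#' @param seed Integer seed.
#' @return A list of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(n_genomes = 61L,
                                 group_sizes = c(WILD = 13L, SP = 11L, SLC = 12L, SLL = 25L),
                                 class_proportions = c(core = 12843, softcore = 3735,
                                                       dispensable = 28790, private = 13698) / 59066,
                                 n_orthogroups = 2000L,
                                 mean_copies = 1.1,
                                 softcore_fraction = 0.99,
                                 private_max_genomes = 1L,
                                 seed = 1L) {
  n_genomes <- check_count(n_genomes, "n_genomes", min = 2L)
  n_orthogroups <- check_count(n_orthogroups, "n_orthogroups", min = 1L)
  if (!setequal(names(group_sizes), TAXON_GROUPS)) {
    stop_config("group_sizes must be named WILD, SP, SLC, SLL")
  }
  if (sum(group_sizes) != n_genomes) {
    stop_config(sprintf("group sizes sum to %d but n_genomes is %d",
                        sum(group_sizes), n_genomes))
  }
  if (!setequal(names(class_proportions), PAN_CLASSES)) {
    stop_config("class_proportions must be named core, softcore, dispensable, private")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop_config("class_proportions must sum to 1")
  }
  if (!is.numeric(mean_copies) || mean_copies < 1) {
    stop_config("mean_copies must be >= 1")
  }
  structure(list(n_genomes = n_genomes,
                 group_sizes = group_sizes[TAXON_GROUPS],
                 class_proportions = class_proportions[PAN_CLASSES],
                 n_orthogroups = n_orthogroups, mean_copies = mean_copies,
                 softcore_fraction = softcore_fraction,
                 private_max_genomes = private_max_genomes, seed = seed),
            class = "pangenome_sim_config")
}

# Occupancy ranges per class under the classifier thresholds; errors when a
# class has an empty range at this genome count.
pan_class_ranges <- function(N, softcore_fraction, private_max_genomes) {
  soft_min <- round(softcore_fraction * N)
  ranges <- list(core = c(N, N),
                 softcore = c(soft_min, N - 1L),
                 dispensable = c(private_max_genomes + 1L, soft_min - 1L),
                 private = c(1L, private_max_genomes))
  ranges
}

#' Simulate an orthogroup table over a genome collection
#'
#' Draws orthogroup occupancies that satisfy their intended pan-gene class
#' exactly: core groups cover all genomes, private groups exactly one (up to
#' `private_max_genomes`), softcore and dispensable groups draw a presence
#' count uniformly over the count range their class occupies under the
#' matching classifier thresholds. Per-class orthogroup counts are allocated
#' deterministically (largest-remainder rounding of the proportions), copy
#' numbers per present genome are geometric with the configured mean
#' (minimum 1), and genes are laid out on one synthetic contig per genome in
#' orthogroup order so ranks and collinearity are well defined. The output
#' is deterministic under a fixed seed.
#'
#' @param config A [pangenome_sim_config()].
#' @return A list with `orthogroups` (`orthogroup_tbl`), `genes` (ranked
#'   gene records over all genomes), `genomes` (genome table) and `truth`
#'   (tibble `group_id`, `class`, `presence_count`).
#' @export
simulate_pangenome <- function(config) {
  if (!inherits(config, "pangenome_sim_config")) {
    stop_config("config must be a pangenome_sim_config")
  }
  N <- config$n_genomes
  ranges <- pan_class_ranges(N, config$softcore_fraction, config$private_max_genomes)
  props <- config$class_proportions
  counts <- floor(props * config$n_orthogroups)
  rem <- config$n_orthogroups - sum(counts)
  if (rem > 0L) {
    extra <- order(props * config$n_orthogroups - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  for (cl in PAN_CLASSES) {
    if (counts[[cl]] > 0L && ranges[[cl]][1L] > ranges[[cl]][2L]) {
      stop_config(sprintf("class '%s' has an empty occupancy range for %d genomes", cl, N))
    }
  }
  groups <- tibble(
    group_id = sprintf("OG%06d", seq_len(config$n_orthogroups)),
    class = factor(rep(PAN_CLASSES, times = counts[PAN_CLASSES]), levels = PAN_CLASSES)
  )
  genomes <- genome_table(
    genome_id = sprintf("%s%02d", rep(names(config$group_sizes), config$group_sizes),
                        unlist(lapply(config$group_sizes, seq_len))),
    taxon_group = rep(names(config$group_sizes), config$group_sizes)
  )
  with_seed(config$seed, {
    membership <- map(seq_len(nrow(groups)), function(i) {
      r <- ranges[[as.character(groups$class[i])]]
      k <- if (r[1L] == r[2L]) r[1L] else sample(seq(r[1L], r[2L]), 1L)
      sort(sample.int(N, k))
    })
    long <- tibble(group_id = rep(groups$group_id, lengths(membership)),
                   genome_idx = unlist(membership))
    p <- 1 / config$mean_copies
    long$copies <- 1L + rgeom(nrow(long), p)
    long$genome_id <- genomes$genome_id[long$genome_idx]
    og <- long |>
      tidyr::uncount(.data$copies) |>
      group_by(.data$genome_id) |>
      arrange(.data$group_id, .by_group = TRUE) |>
      mutate(gene_id = sprintf("%s_g%05d", .data$genome_id[1L], seq_len(n()))) |>
      ungroup()
    genes <- og |>
      group_by(.data$genome_id) |>
      arrange(.data$group_id, .by_group = TRUE) |>
      mutate(seq_region = "chr1",
             start = 1000L * (seq_len(n()) - 1L) + 1L,
             end = .data$start + 500L,
             strand = "+") |>
      ungroup() |>
      select("gene_id", "genome_id", "seq_region", "start", "end", "strand") |>
      add_gene_ranks()
    orthogroups <- as_orthogroup_tbl(
      og |> select("group_id", "genome_id", "gene_id") |> arrange(.data$group_id),
      genome_ids = genomes$genome_id
    )
    truth <- groups |>
      left_join(long |> count(.data$group_id, name = "presence_count"), by = "group_id")
    list(orthogroups = orthogroups, genes = genes, genomes = genomes, truth = truth)
  })
}
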
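# End-to-end orchestration on synthetic (or user) inputs, writing one TSV
# per stage plus a manifest, and rendering the summary tables.

#' Pipeline run configuration
#'
#' Declarative configuration of a full synthetic-data run. Thresholds
#' default to the analysis parameters used throughout the package: minimum
#' collinear block 15 anchors, kappa 2.5 and initial omega 0.2 for the
#' codon models, alpha 0.01 for the selection LRTs and 0.05 for
#' enrichment. The softcore fraction defaults to 0.9 here because the
#' demonstration run uses a small genome collection, for which the 0.99
#' production threshold leaves no feasible softcore occupancy range; the
#' same fraction is applied to the generator and the classifier.
#'
#' @param sim A [pangenome_sim_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @param softcore_fraction,private_max_genomes Classifier thresholds.
#' @param n_permutations Rarefaction orderings.
#' @param enrichment_alpha,selection_alpha Significance thresholds.
#' @param min_block,max_tandem_gap Duplication-stage parameters.
#' @param n_tandem_arrays,n_wgd_blocks,wgd_block_length Implanted signal.
#' @param n_kaks_pairs Simulated ortholog pairs for the Ka/Ks stage.
#' @param n_selection_groups,selection_codons Orthogroups and codon sites
#'   for the selection stage.
#' @param annotations_path,orthogroups_path Optional user-supplied inputs
#'   replacing the synthetic ones; checked before any compute.
#' @return A list of class `pan_run_config`.
#' @export
run_config <- function(sim = pangenome_sim_config(n_genomes = 12L,
                                                  group_sizes = c(WILD = 3L, SP = 3L, SLC = 3L, SLL = 3L),
                                                  n_orthogroups = 300L,
                                                  mean_copies = 1,
                                                  seed = 1L),
                       seed = 1L, out_dir = tempfile("panortho_run_"),
                       softcore_fraction = 0.9, private_max_genomes = 1L,
                       n_permutations = 50L,
                       enrichment_alpha = 0.05, selection_alpha = 0.01,
                       min_block = 15L, max_tandem_gap = 0L,
                       n_tandem_arrays = 3L, n_wgd_blocks = 1L,
                       wgd_block_length = 20L,
                       n_kaks_pairs = 10L,
                       n_selection_groups = 3L, selection_codons = 60L,
                       annotations_path = NULL, orthogroups_path = NULL) {
  structure(list(sim = sim, seed = seed, out_dir = out_dir,
                 softcore_fraction = softcore_fraction,
                 private_max_genomes = private_max_genomes,
                 n_permutations = n_permutations,
                 enrichment_alpha = enrichment_alpha,
                 selection_alpha = selection_alpha,
                 min_block = min_block, max_tandem_gap = max_tandem_gap,
                 n_tandem_arrays = n_tandem_arrays,
                 n_wgd_blocks = n_wgd_blocks,
                 wgd_block_length = wgd_block_length,
                 n_kaks_pairs = n_kaks_pairs,
                 n_selection_groups = n_selection_groups,
                 selection_codons = selection_codons,
                 annotations_path = annotations_path,
                 orthogroups_path = orthogroups_path),
            class = "pan_run_config")
}

#' Run the full pipeline
#'
#' Executes classification, rarefaction and openness, PAV, enrichment,
#' duplication, Ka/Ks, selection and the LRR-RLK cascade on a simulated
#' pangenome (or user inputs where configured), writing one TSV per stage
#' plus a JSON manifest recording the package version, configuration hash,
#' seed and per-file checksums. A stage failure halts the run naming the
#' stage; previously written outputs are kept. Reruns with the same
#' configuration and seed produce byte-identical stage outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "pan_run_config")) stop_config("config must be a run_config()")
  # pre-flight: declared input files must exist before any compute
  for (p in c(config$annotations_path, config$orthogroups_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_config(sprintf("pre-flight: input file '%s' does not exist", p))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  files <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "panortho_stage_error", parent = e)
    })
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(df), path, progress = FALSE)
    files <<- c(files, path)
    path
  }

  results$sim <- stage("simulate", {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    # generator occupancies must satisfy the classifier thresholds in force
    sim_cfg$softcore_fraction <- config$softcore_fraction
    sim_cfg$private_max_genomes <- config$private_max_genomes
    simulate_pangenome(sim_cfg)
  })
  sim <- results$sim
  genomes <- sim$genomes

  results$classes <- stage("classify", {
    occ <- build_occupancy(sim$orthogroups)
    cl <- classify_pangene_sets(occ, pan_class_thresholds(config$softcore_fraction,
                                                          config$private_max_genomes))
    emit(cl, "classes")
    emit(pan_class_summary(cl), "class_summary")
    cl
  })
  occ <- build_occupancy(sim$orthogroups)

  results$rarefaction <- stage("rarefy", {
    curves <- rarefaction_curves(occ, config$n_permutations, seed = config$seed + 1L)
    emit(curves, "rarefaction")
    fit <- fit_openness(curves)
    emit(tidy(fit), "openness")
    list(curves = curves, fit = fit)
  })

  results$pav <- stage("pav", {
    spec <- group_specific_orthogroups(occ, genomes, classes = results$classes)
    emit(spec, "group_specific")
    spec
  })

  results$enrichment <- stage("enrichment", {
    ann <- if (!is.null(config$annotations_path)) {
      read_annotations(config$annotations_path)
    } else {
      genes <- sim$genes$gene_id
      fg <- genes[seq_len(min(100L, length(genes)))]
      spike_annotation_enrichment(genes, "PF00069", fg, odds = 10,
                                  baseline_rate = 0.02, seed = config$seed + 2L)
    }
    genes <- attr(ann, "gene_universe")
    fg <- genes[seq_len(min(100L, length(genes)))]
    enr <- fisher_enrichment(fg, ann, term_kind = "pfam",
                             alpha = config$enrichment_alpha)
    emit(enr, "enrichment")
    enr
  })

  results$duplication <- stage("duplication", {
    outgroup <- genomes$genome_id[nrow(genomes)]
    imp <- implant_duplications(sim, outgroup_id = outgroup,
                                n_tandem_arrays = config$n_tandem_arrays,
                                n_wgd_blocks = config$n_wgd_blocks,
                                block_length = config$wgd_block_length,
                                seed = config$seed + 3L)
    tand <- find_tandem_arrays(imp$genes, imp$orthogroups, config$max_tandem_gap)
    anch <- orthogroup_anchors(imp$orthogroups, imp$genes,
                               imp$target_genome, outgroup)
    blocks <- chain_collinear_blocks(anch, min_block = config$min_block)
    labels <- classify_duplicates(imp$genes, imp$orthogroups, blocks, tand,
                                  imp$target_genome)
    emit(labels |> select(-dplyr::any_of("evidence")), "duplication_labels")
    gene_classes <- imp$orthogroups |>
      left_join(as_tibble(results$classes) |> select("group_id", "pan_class"),
                by = "group_id") |>
      select("gene_id", "pan_class")
    summ <- summarize_duplication(labels, gene_classes, genomes)
    if (!is.null(summ$by_pan_set)) emit(summ$by_pan_set, "duplication_by_set")
    list(labels = labels, summary = summ, truth = imp$truth_labels)
  })

  results$kaks <- stage("kaks", {
    tree <- ape::read.tree(text = "(A:0.4,B:0.4);")
    recs <- map(seq_len(config$n_kaks_pairs), function(i) {
      simc <- codon_sim_config(tree, branch_omega = 0.2, n_codons = 200L,
                               seed = config$seed + 10L + i)
      aln <- simulate_codon_alignment(simc)$alignment
      kaks_pair(aln[["A"]], aln[["B"]],
                gene_a = sprintf("pair%02d_A", i), gene_b = sprintf("pair%02d_B", i))
    }) |> list_rbind()
    emit(recs, "kaks")
    recs
  })

  results$selection <- stage("selection", {
    tree <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1,(E:0.2,F:0.2):0.1);")
    fg <- c("A", "B")
    fits <- lapply(seq_len(config$n_selection_groups), function(i) {
      om <- if (i == 1L) list(foreground = fg, fg = 1.5, bg = 0.2) else 0.2
      simc <- codon_sim_config(tree, branch_omega = om,
                               n_codons = config$selection_codons,
                               seed = config$seed + 20L + i)
      aln <- simulate_codon_alignment(simc)$alignment
      fit_branch_models(tree, aln, foreground = fg, fit_h2 = TRUE)
    })
    names(fits) <- sprintf("OG_SEL%02d", seq_along(fits))
    calls <- call_rapid_and_positive(fits, alpha = config$selection_alpha)
    emit(calls, "selection")
    calls
  })

  results$lrr <- stage("lrrrlk", {
    # synthetic domain architecture over a subset of simulated proteins
    prot <- head(sim$genes$gene_id, 50L)
    hits <- with_seed(config$seed + 30L, {
      is_rlk <- rbinom(length(prot), 1L, 0.4) == 1L
      bind_rows(
        tibble(protein_id = prot, domain_id = KINASE_PFAM,
               domain_class = "KINASE", start = 400L, end = 650L,
               passes_cutoff = TRUE),
        tibble(protein_id = prot[is_rlk], domain_id = "PF00560",
               domain_class = "LRR", start = 40L, end = 70L,
               passes_cutoff = TRUE),
        tibble(protein_id = prot[is_rlk], domain_id = "",
               domain_class = "TM", start = 330L, end = 355L,
               passes_cutoff = TRUE)
      )
    })
    cands <- classify_lrr_rlk(hits)
    refs <- tibble(reference_id = sprintf("AT%02d", seq_along(LRR_SUBFAMILIES[1:19])),
                   subfamily = LRR_SUBFAMILIES[1:19])
    dists <- with_seed(config$seed + 31L, {
      tidyr::expand_grid(protein_id = cands$protein_id,
                         reference_id = refs$reference_id) |>
        mutate(distance = runif(n(), 0.1, 1.6))
    })
    rec <- assign_subfamily(cands, dists, refs)
    emit(rec, "lrr_rlkome")
    rec
  })

  manifest <- list(
    package = "panortho",
    version = as.character(utils::packageVersion("panortho")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest, out_dir = config$out_dir)))
}

#' Render the duplication and selection summary tables
#'
#' Produces the two headline report tables: the per-pan-gene-set
#' duplication table (totals, WGD and TD counts with percentages at two
#' decimal places) and the per-foreground selection table (numbers of
#' rapidly evolving and positively selected genes). Counts are
#' cross-checked: a per-set table whose totals disagree with the supplied
#' gene universe raises an integrity error.
#'
#' @param dup_by_set Tibble `gene_set`, `total_genes`, `wgd_genes`,
#'   `td_genes` (percent columns recomputed here).
#' @param selection_counts Optional tibble `foreground`,
#'   `n_rapidly_evolving`, `n_positively_selected`.
#' @param expected_total Optional known gene-universe size for the
#'   integrity check.
#' @return A list with `table1` and `table2` tibbles.
#' @export
render_summary_tables <- function(dup_by_set, selection_counts = NULL,
                                  expected_total = NULL) {
  t1 <- duplication_rate_table(dup_by_set$gene_set, dup_by_set$total_genes,
                               dup_by_set$wgd_genes, dup_by_set$td_genes)
  if (!is.null(expected_total) && sum(t1$total_genes) != expected_total) {
    abort(sprintf("integrity error: per-set totals (%d) do not reconstruct the gene universe (%d)",
                  sum(t1$total_genes), expected_total),
          class = "panortho_integrity_error")
  }
  t2 <- NULL
  if (!is.null(selection_counts)) {
    t2 <- as_tibble(selection_counts)
  }
  list(table1 = t1, table2 = t2)
}
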
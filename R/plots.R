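# ggplot2 display methods for the main result types.

#' @describeIn classify_pangene_sets Composition bar chart of the four
#'   pan-gene sets (orthogroup counts with percentage labels).
#' @param object A `pan_classification`.
#' @param ... Ignored.
#' @export
autoplot.pan_classification <- function(object, ...) {
  df <- pan_class_summary(object)
  ggplot(df, aes(x = .data$pan_class, y = .data$n_groups, fill = .data$pan_class)) +
    geom_col(show.legend = FALSE) +
    ggplot2::geom_text(aes(label = sprintf("%.1f%%", .data$share_pct)),
                       vjust = -0.4, size = 3) +
    labs(x = NULL, y = "orthogroups",
         title = "Pan-gene set composition") +
    theme_minimal()
}

#' @describeIn rarefaction_curves Pan- and core-genome rarefaction curves
#'   with min-max ribbons.
#' @param object A `pan_rarefaction`.
#' @param ... Ignored.
#' @export
autoplot.pan_rarefaction <- function(object, ...) {
  df <- bind_rows(
    tibble(n = object$n, mean = object$pan_mean, lo = object$pan_min,
           hi = object$pan_max, curve = "pan"),
    tibble(n = object$n, mean = object$core_mean, lo = object$core_min,
           hi = object$core_max, curve = "core")
  )
  ggplot(df, aes(x = .data$n, y = .data$mean, colour = .data$curve,
                 fill = .data$curve)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.2,
                colour = NA) +
    geom_line() +
    labs(x = "genomes sampled", y = "orthogroups",
         title = "Pan- and core-genome size") +
    theme_minimal()
}

#' @describeIn fisher_enrichment Dot plot of enriched terms
#'   (-log10 adjusted p against foreground hit count).
#' @param object An `enrichment_tbl`.
#' @param top Number of top terms to show.
#' @param ... Ignored.
#' @export
autoplot.enrichment_tbl <- function(object, top = 20L, ...) {
  df <- head(object, top)
  ggplot(df, aes(x = -log10(.data$p_adjusted),
                 y = stats::reorder(.data$term_id, -.data$p_adjusted),
                 size = .data$k_fg, colour = .data$enriched)) +
    geom_point() +
    labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
         title = "Term enrichment") +
    theme_minimal()
}

#' @describeIn gene_pav_report Presence/absence tile map of target
#'   orthogroups across genomes, shaded by copy number.
#' @param object A `pav_report`.
#' @param ... Ignored.
#' @export
autoplot.pav_report <- function(object, ...) {
  ggplot(object, aes(x = .data$genome_id, y = .data$group_id,
                     fill = .data$n_genes)) +
    geom_tile(colour = "grey80") +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "copies",
         title = "Presence/absence variation") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Boxplot of Ka/Ks ratios by pan-gene set
#'
#' @param records A `kaks_tbl`.
#' @param classes Tibble mapping `gene_id` to `pan_class`.
#' @return A ggplot object.
#' @export
plot_kaks_sets <- function(records, classes) {
  df <- records |>
    left_join(classes |> select(gene_id = 1L, pan_class = 2L),
              by = c(gene_a = "gene_id")) |>
    filter(!is.na(.data$ratio))
  ggplot(df, aes(x = .data$pan_class, y = .data$ratio, fill = .data$pan_class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    labs(x = NULL, y = "Ka/Ks", title = "Divergence by pan-gene set") +
    theme_minimal()
}
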
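# Nei-Gojobori (NG86) Ka/Ks on codon-aligned ortholog pairs, with
# Jukes-Cantor multiple-hit correction and a Fisher exact significance test
# on the sites-vs-differences table.

# Per-codon synonymous site counts, memoized: S_codon = 3 * (synonymous
# single-base mutations) / (single-base mutations not creating a stop).
codon_site_table <- function() {
  if (!is.null(codon_env$sites)) return(codon_env$sites)
  tab <- codon_tables()
  n <- length(tab$codons)
  S <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours within the sense codons
    js <- which(tab$pos[i, ] > 0L)
    n_sense <- length(js)              # mutations not creating a stop (of 9)
    n_syn <- sum(tab$syn[i, js])
    S[i] <- if (n_sense > 0L) 3 * n_syn / n_sense else 0
  }
  codon_env$sites <- setNames(S, tab$codons)
  codon_env$sites
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' For every codon, the 9 single-base mutations are classified as synonymous
#' or nonsynonymous; mutations creating a stop codon are excluded from both
#' numerator and denominator. A codon contributes `3 * f_syn` synonymous
#' sites; counts are summed over codons, so `S + N = 3 * n_codons` always.
#'
#' @param codon_sequence A coding sequence (length divisible by 3, no
#'   internal stop codons; a terminal stop codon is dropped).
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
count_sites <- function(codon_sequence) {
  tab <- codon_tables()
  cod <- split_codons(codon_sequence)
  if (length(cod) && cod[length(cod)] %in% tab$stops) cod <- cod[-length(cod)]
  bad <- which(cod %in% tab$stops)
  if (length(bad)) {
    stop_validate(sprintf("internal stop codon at codon index %d", bad[1L]))
  }
  unknown <- which(!(cod %in% tab$codons))
  if (length(unknown)) {
    stop_validate(sprintf("unrecognized codon '%s' at index %d", cod[unknown[1L]], unknown[1L]))
  }
  S <- sum(codon_site_table()[cod])
  c(S = S, N = 3 * length(cod) - S)
}

#' Nei-Gojobori pathway-averaged difference counts for one codon pair
#'
#' Codons differing at `d` positions are compared by enumerating all `d!`
#' orderings of the single-base steps between them; paths passing through a
#' stop codon are discarded, and synonymous/nonsynonymous step counts are
#' averaged over the remaining paths (so `sd + nd = d` whenever at least one
#' valid path exists).
#'
#' @param codon_a,codon_b Length-3 codon strings, gap-free.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; both `NA` (with a
#'   warning) when every path passes through a stop codon.
#' @export
count_differences <- function(codon_a, codon_b) {
  tab <- codon_tables()
  a <- strsplit(toupper(codon_a), "")[[1L]]
  b <- strsplit(toupper(codon_b), "")[[1L]]
  if (length(a) != 3L || length(b) != 3L) stop_validate("codons must have length 3")
  diffs <- which(a != b)
  d <- length(diffs)
  if (d == 0L) return(c(sd = 0, nd = 0))
  aa <- tab$aa
  orders <- permutations_lex(d)
  tot_s <- 0; tot_n <- 0; n_paths <- 0L
  for (ord in orders) {
    cur <- a
    s <- 0L; nn <- 0L
    valid <- TRUE
    for (p in diffs[ord]) {
      nxt <- cur
      nxt[p] <- b[p]
      c_from <- paste(cur, collapse = "")
      c_to <- paste(nxt, collapse = "")
      if (c_to %in% tab$stops || c_from %in% tab$stops) { valid <- FALSE; break }
      if (aa[[c_from]] == aa[[c_to]]) s <- s + 1L else nn <- nn + 1L
      cur <- nxt
    }
    if (valid) {
      tot_s <- tot_s + s; tot_n <- tot_n + nn; n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) {
    warn(sprintf("no stop-free mutational path between %s and %s; codon pair excluded",
                 codon_a, codon_b))
    return(c(sd = NA_real_, nd = NA_real_))
  }
  c(sd = tot_s / n_paths, nd = tot_n / n_paths)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for one aligned codon pair
#'
#' Computes synonymous (`S`) and nonsynonymous (`N`) site counts (averaged
#' over the two sequences), pathway-averaged difference counts (`Sd`, `Nd`),
#' the proportions `ps = Sd/S` and `pn = Nd/N`, Jukes-Cantor-corrected rates
#' `Ks` and `Ka`, their ratio, and a two-sided Fisher exact p-value on the
#' rounded 2x2 table of sites versus differences. Codon columns containing a
#' gap in either sequence are removed pairwise first.
#'
#' @param seq_a,seq_b Aligned coding sequences of equal length.
#' @param gene_a,gene_b Optional identifiers carried into the output.
#' @return A one-row tibble of class `kaks_tbl` with columns `gene_a`,
#'   `gene_b`, `n_codons`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ka`, `ks`,
#'   `ratio`, `fisher_p`. Rates are `NA` where the correction is undefined
#'   (`p >= 3/4` or zero sites); `ratio` is `NA` unless both rates are
#'   finite and `ks > 0`.
#' @export
kaks_pair <- function(seq_a, seq_b, gene_a = "a", gene_b = "b") {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop_validate("aligned sequences differ in codon length")
  tab <- codon_tables()
  # drop terminal stop codons, then pairwise-remove gapped codons
  n <- length(ca)
  if (n && (ca[n] %in% tab$stops || cb[n] %in% tab$stops)) {
    ca <- ca[-n]; cb <- cb[-n]
  }
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  sites_a <- count_sites(paste(ca, collapse = ""))
  sites_b <- count_sites(paste(cb, collapse = ""))
  S <- (sites_a["S"] + sites_b["S"]) / 2
  N <- (sites_a["N"] + sites_b["N"]) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- count_differences(ca[i], cb[i])
    if (anyNA(d)) next
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- if (is.na(ps)) NA_real_ else jc_correct(ps)
  ka <- if (is.na(pn)) NA_real_ else jc_correct(pn)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  tab2 <- matrix(round(c(Sd, S - Sd, Nd, N - Nd)), nrow = 2L, byrow = TRUE)
  fisher_p <- if (all(tab2 >= 0) && sum(tab2) > 0) {
    fisher.test(tab2)$p.value
  } else {
    NA_real_
  }
  out <- tibble(gene_a = gene_a, gene_b = gene_b, n_codons = length(ca),
                S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
                ps = unname(ps), pn = unname(pn), ka = unname(ka),
                ks = unname(ks), ratio = unname(ratio),
                fisher_p = unname(fisher_p))
  class(out) <- c("kaks_tbl", class(tibble()))
  out
}

#' Batch Ka/Ks over a table of ortholog pairs
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param seqs_a,seqs_b Named character vectors of aligned coding sequences
#'   (names matching the pair gene ids; each pair must be mutually aligned).
#' @return A `kaks_tbl` with one row per pair.
#' @export
kaks_pairs <- function(pairs, seqs_a, seqs_b = seqs_a) {
  rows <- pmap(list(pairs$gene_a, pairs$gene_b), function(a, b) {
    kaks_pair(seqs_a[[a]], seqs_b[[b]], gene_a = a, gene_b = b)
  })
  out <- list_rbind(rows)
  class(out) <- c("kaks_tbl", class(tibble()))
  out
}

#' Aggregate Ka/Ks records by pan-gene set
#'
#' Summarises Ka, Ks and Ka/Ks per pan-gene class and compares the ratio
#' distributions between classes by two-sided Mann-Whitney tests with
#' Benjamini-Hochberg adjustment. Records with an undefined ratio are
#' excluded from summaries and counted.
#'
#' @param records A `kaks_tbl`.
#' @param classes Tibble mapping `gene_id` to `pan_class` (the `gene_a` side
#'   of each record is looked up).
#' @return A list with `summary` (per-class n, exclusions, means, medians)
#'   and `comparisons` (pairwise Mann-Whitney p-values, BH-adjusted;
#'   classes with fewer than two defined ratios are skipped).
#' @export
aggregate_by_set <- function(records, classes) {
  joined <- records |>
    left_join(classes |> select(gene_id = 1L, pan_class = 2L), by = c(gene_a = "gene_id"))
  summary <- joined |>
    group_by(.data$pan_class) |>
    summarise(
      n_pairs = n(),
      n_undefined = sum(is.na(.data$ratio)),
      mean_ka = mean(.data$ka, na.rm = TRUE),
      mean_ks = mean(.data$ks, na.rm = TRUE),
      mean_ratio = mean(.data$ratio, na.rm = TRUE),
      median_ratio = median(.data$ratio, na.rm = TRUE),
      .groups = "drop"
    )
  defined <- joined |> filter(!is.na(.data$ratio), !is.na(.data$pan_class))
  sets <- defined |> count(.data$pan_class) |> filter(n >= 2L) |> pull(.data$pan_class)
  comparisons <- tibble(set_a = character(), set_b = character(), p_value = numeric())
  if (length(sets) >= 2L) {
    combos <- combn(as.character(sets), 2L)
    comparisons <- map(seq_len(ncol(combos)), function(k) {
      a <- combos[1L, k]; b <- combos[2L, k]
      p <- suppressWarnings(wilcox.test(
        defined$ratio[defined$pan_class == a],
        defined$ratio[defined$pan_class == b]
      )$p.value)
      tibble(set_a = a, set_b = b, p_value = p)
    }) |> list_rbind()
    comparisons$p_adjusted <- p.adjust(comparisons$p_value, method = "BH")
  }
  list(summary = summary, comparisons = comparisons)
}
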
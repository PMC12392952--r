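# Shared fixtures and independent oracles, built in code at test time.

three_genomes <- function() {
  genome_table(c("gA", "gB", "gC"), c("WILD", "SP", "SLL"))
}

# Write an OrthoFinder-dialect orthogroup file from a named list:
# list(OG1 = list(gA = c("a1","a2"), gB = "b1"), ...)
write_og_file <- function(groups, genome_ids, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("Orthogroup", genome_ids), collapse = "\t")
  rows <- vapply(names(groups), function(g) {
    cells <- vapply(genome_ids, function(gid) {
      genes <- groups[[g]][[gid]]
      if (is.null(genes)) "" else paste(genes, collapse = ", ")
    }, character(1L))
    paste(c(g, cells), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  path
}

write_gff_file <- function(df, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     df$seq_region, df$start, df$end,
                     ifelse(is.na(df$strand), ".", df$strand), df$gene_id))
  writeLines(lines, path)
  path
}

# Small simulated pangenome shared by several tests.
small_sim <- function(seed = 5L, n_orthogroups = 300L, mean_copies = 1) {
  cfg <- pangenome_sim_config(
    n_genomes = 12L, group_sizes = c(WILD = 3L, SP = 3L, SLC = 3L, SLL = 3L),
    n_orthogroups = n_orthogroups, mean_copies = mean_copies,
    softcore_fraction = 0.9, seed = seed
  )
  simulate_pangenome(cfg)
}

# All-core pangenome with one genome usable as a collinearity outgroup.
core_sim <- function(seed = 2L, n_orthogroups = 400L) {
  cfg <- pangenome_sim_config(
    n_genomes = 4L, group_sizes = c(WILD = 1L, SP = 1L, SLC = 1L, SLL = 1L),
    class_proportions = c(core = 1, softcore = 0, dispensable = 0, private = 0),
    n_orthogroups = n_orthogroups, mean_copies = 1,
    softcore_fraction = 0.9, seed = seed
  )
  simulate_pangenome(cfg)
}

# ---- independent oracles -------------------------------------------------

# hypergeometric upper tail P(X >= k) by direct binomial-coefficient sums
oracle_hyper_tail <- function(k, K, n, m) {
  xs <- seq(max(0L, k), min(K, m))
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(n - K, m - xs) - lchoose(n, m)))
}

# slow NG86 site counter: re-derives the genetic code independently of the
# package's cached neighbour tables
oracle_ng86_sites <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  S <- 0
  for (cod in codons) {
    chars <- strsplit(cod, "")[[1]]
    syn <- 0L; valid <- 0L
    for (p in 1:3) for (nt in setdiff(nts, chars[p])) {
      mut <- chars; mut[p] <- nt
      mv <- paste(mut, collapse = "")
      if (gc[[mv]] == "*") next
      valid <- valid + 1L
      if (gc[[mv]] == gc[[cod]]) syn <- syn + 1L
    }
    if (valid > 0L) S <- S + 3 * syn / valid
  }
  c(S = S, N = 3 * length(codons) - S)
}

# slow NG86 pathway counter for one codon pair
oracle_ng86_diffs <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(1L) else if (d == 2L) list(1:2, 2:1) else
    list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  tot_s <- 0; tot_n <- 0; nv <- 0L
  for (pm in perms) {
    cur <- ca; s <- 0L; nn <- 0L; ok <- TRUE
    for (p in pos[pm]) {
      nxt <- cur; nxt[p] <- cb[p]
      f <- paste(cur, collapse = ""); t <- paste(nxt, collapse = "")
      if (gc[[f]] == "*" || gc[[t]] == "*") { ok <- FALSE; break }
      if (gc[[f]] == gc[[t]]) s <- s + 1L else nn <- nn + 1L
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + nn; nv <- nv + 1L }
  }
  if (nv == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_s / nv, nd = tot_n / nv)
}

random_codon_seq <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# standard 6-taxon test tree with an (A,B) foreground clade
six_taxon_tree <- function() {
  ape::read.tree(text = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1,(E:0.2,F:0.2):0.1);")
}
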
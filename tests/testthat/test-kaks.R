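test_that("site counting matches enumeration on canonical codons", {
  # phenylalanine TTT: only TTC is synonymous among 9 mutations
  expect_equal(unname(count_sites("TTT")), c(1 / 3, 8 / 3), tolerance = 1e-12)
  # tryptophan TGG: no synonymous neighbour (two mutations hit stops)
  expect_equal(unname(count_sites("TGG"))[1], 0)
  # conservation S + N = 3L on random sequences
  set.seed(11)
  for (i in 1:10) {
    s <- random_codon_seq(25)
    sn <- count_sites(s)
    expect_equal(unname(sn["S"] + sn["N"]), 3 * 25, tolerance = 1e-9)
  }
  expect_error(count_sites("TTTTAAGGG"), regexp = "codon index 2",
               class = "panortho_validation_error")
})

test_that("difference counting averages over mutational pathways", {
  expect_equal(unname(count_differences("TTT", "TTC")), c(1, 0))
  expect_equal(unname(count_differences("AAA", "AAA")), c(0, 0))
  # two-difference pair, both orderings enumerated by hand:
  # TTT -> GTT(Val) -> GTA(Val): nonsyn then syn
  # TTT -> TTA(Leu) -> GTA(Val): nonsyn then nonsyn
  # average sd = 0.5, nd = 1.5
  expect_equal(unname(count_differences("TTT", "GTA")), c(0.5, 1.5))
  # agreement with the independent oracle on random codon pairs
  set.seed(13)
  tab_codons <- strsplit(random_codon_seq(200), "")[[1]]
  for (i in 1:40) {
    a <- substr(random_codon_seq(1), 1, 3)
    b <- substr(random_codon_seq(1), 1, 3)
    got <- suppressWarnings(count_differences(a, b))
    want <- oracle_ng86_diffs(a, b)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!anyNA(got)) expect_equal(unname(got["sd"] + got["nd"]), d)
  }
})

test_that("pairwise Ka/Ks agrees with the slow oracle on random pairs", {
  set.seed(17)
  for (i in 1:20) {
    a <- random_codon_seq(30)
    # derive b by mutating a few sites to keep ps, pn in the defined range
    b_chars <- strsplit(a, "")[[1]]
    idx <- sample(length(b_chars), 6)
    b_chars[idx] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    b <- paste(b_chars, collapse = "")
    gc <- Biostrings::GENETIC_CODE
    cods <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (any(gc[cods(b)] == "*")) next
    rec <- suppressWarnings(kaks_pair(a, b))
    sa <- oracle_ng86_sites(a); sb <- oracle_ng86_sites(b)
    S <- (sa["S"] + sb["S"]) / 2; N <- (sa["N"] + sb["N"]) / 2
    Sd <- 0; Nd <- 0
    ca <- cods(a); cb <- cods(b)
    for (k in seq_along(ca)) {
      d <- oracle_ng86_diffs(ca[k], cb[k])
      if (!anyNA(d)) { Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"] }
    }
    expect_equal(rec$S, unname(S), tolerance = 1e-10)
    expect_equal(rec$N, unname(N), tolerance = 1e-10)
    expect_equal(rec$Sd, unname(Sd), tolerance = 1e-10)
    expect_equal(rec$Nd, unname(Nd), tolerance = 1e-10)
    ps <- Sd / S; pn <- Nd / N
    if (ps < 0.75) expect_equal(rec$ks, unname(-0.75 * log(1 - 4 * ps / 3)),
                                tolerance = 1e-10)
    # symmetry
    rec_ba <- suppressWarnings(kaks_pair(b, a))
    expect_equal(rec_ba$ka, rec$ka, tolerance = 1e-12)
    expect_equal(rec_ba$ks, rec$ks, tolerance = 1e-12)
  }
})

test_that("identical sequences give zero rates and an undefined ratio", {
  s <- random_codon_seq(40)
  rec <- kaks_pair(s, s)
  expect_equal(rec$ka, 0)
  expect_equal(rec$ks, 0)
  expect_true(is.na(rec$ratio))
})

test_that("fisher significance matches the exact-table computation", {
  # the 2x2 table (2, 38, 10, 100) as sites-vs-differences
  p_pkg <- fisher.test(matrix(c(2, 38, 10, 100), nrow = 2, byrow = TRUE))$p.value
  # independent enumeration: sum of hypergeometric point masses <= observed
  m <- matrix(c(2, 38, 10, 100), nrow = 2, byrow = TRUE)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  dh <- function(x) exp(lchoose(cs[1], x) + lchoose(cs[2], rs[1] - x) - lchoose(n, rs[1]))
  xs <- max(0, rs[1] - cs[2]):min(cs[1], rs[1])
  probs <- vapply(xs, dh, numeric(1))
  p_oracle <- sum(probs[probs <= dh(m[1, 1]) * (1 + 1e-7)])
  expect_equal(p_pkg, unname(p_oracle), tolerance = 1e-9)
})

test_that("simulated pairs recover the generating selection regime", {
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  ratios <- vapply(1:12, function(i) {
    cfg <- codon_sim_config(tree, branch_omega = 0.2, n_codons = 1000L,
                            seed = 300L + i)
    aln <- simulate_codon_alignment(cfg)$alignment
    kaks_pair(aln[["A"]], aln[["B"]])$ratio
  }, numeric(1L))
  expect_true(median(ratios, na.rm = TRUE) > 0.1 &&
                median(ratios, na.rm = TRUE) < 0.35)
})

test_that("estimated Ks grows with branch length", {
  tree_at <- function(t) ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
  lens <- seq(0.05, 1.2, length.out = 8)
  ks <- vapply(seq_along(lens), function(i) {
    cfg <- codon_sim_config(tree_at(lens[i]), branch_omega = 0.2,
                            n_codons = 1000L, seed = 500L + i)
    aln <- simulate_codon_alignment(cfg)$alignment
    kaks_pair(aln[["A"]], aln[["B"]])$ks
  }, numeric(1L))
  expect_gt(cor(lens, ks, method = "spearman"), 0.9)
})

test_that("set-level aggregation summarises and compares distributions", {
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  sim_set <- function(omega, n, seed0, prefix) {
    recs <- lapply(seq_len(n), function(i) {
      cfg <- codon_sim_config(tree, branch_omega = omega, n_codons = 300L,
                              seed = seed0 + i)
      aln <- simulate_codon_alignment(cfg)$alignment
      kaks_pair(aln[["A"]], aln[["B"]],
                gene_a = sprintf("%s_%03d", prefix, i), gene_b = "vv")
    })
    dplyr::bind_rows(recs)
  }
  recs <- dplyr::bind_rows(sim_set(0.1, 40, 700, "core"),
                           sim_set(0.45, 40, 800, "disp"))
  classes <- tibble::tibble(
    gene_id = recs$gene_a,
    pan_class = ifelse(grepl("^core", recs$gene_a), "core", "dispensable"))
  agg <- aggregate_by_set(recs, classes)
  s <- agg$summary
  expect_lt(s$mean_ratio[s$pan_class == "core"],
            s$mean_ratio[s$pan_class == "dispensable"])
  expect_lt(agg$comparisons$p_value[1], 0.01)
  # one-record set: summary exists, comparison skipped
  one <- sim_set(0.2, 1, 900, "solo")
  agg1 <- aggregate_by_set(one, tibble::tibble(gene_id = one$gene_a,
                                               pan_class = "private"))
  expect_equal(agg1$summary$n_pairs, 1L)
  expect_equal(nrow(agg1$comparisons), 0L)
  # all-undefined set: exclusion counted, no error
  s0 <- random_codon_seq(30)
  undef <- kaks_pair(s0, s0, gene_a = "u1")
  aggu <- aggregate_by_set(undef, tibble::tibble(gene_id = "u1", pan_class = "core"))
  expect_equal(aggu$summary$n_undefined, 1L)
})
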
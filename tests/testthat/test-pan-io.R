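test_that("orthogroup reader merges unassigned genes as singletons", {
  genomes <- three_genomes()
  assigned <- write_og_file(list(
    OG1 = list(gA = c("a1", "a2"), gB = "b1", gC = "c1"),
    OG2 = list(gA = "a3", gB = "b2")
  ), genomes$genome_id)
  unassigned <- write_og_file(list(
    OG9 = list(gC = "c9")
  ), genomes$genome_id)
  og <- read_orthogroups(assigned, unassigned, genomes)
  expect_equal(length(unique(og$group_id)), 3L)
  expect_equal(og$genome_id[og$gene_id == "c9"], "gC")
  expect_equal(sum(og$group_id == "OG9"), 1L)
  expect_equal(nrow(og), 7L)
})

test_that("orthogroup reader enforces its contracts", {
  genomes <- three_genomes()
  # header genome absent from the genome table
  bad_header <- write_og_file(list(OG1 = list(gA = "a1")), c("gA", "gZ"))
  expect_error(read_orthogroups(bad_header, genomes = genomes),
               class = "panortho_config_error")
  # one gene listed in two groups
  groups <- c(list(OG0 = list(gA = "dup1", gB = "b0")),
              setNames(lapply(1:9, function(i) list(gA = paste0("a", i))),
                       paste0("OGX", 1:9)))
  groups$OGX5$gB <- "dup1"
  dup_file <- write_og_file(groups, genomes$genome_id)
  expect_error(read_orthogroups(dup_file, genomes = genomes),
               class = "panortho_validation_error")
})

test_that("orthogroup table round-trips through the writer", {
  sim <- small_sim(seed = 11, n_orthogroups = 50)
  path <- tempfile(fileext = ".tsv")
  write_orthogroups(sim$orthogroups, path)
  back <- read_orthogroups(path, genomes = sim$genomes)
  orig <- dplyr::arrange(tibble::as_tibble(sim$orthogroups),
                         group_id, genome_id, gene_id)
  got <- dplyr::arrange(tibble::as_tibble(back), group_id, genome_id, gene_id)
  expect_equal(got, orig)
})

test_that("gene ranks are recomputed per region and order-invariant", {
  df <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), seq_region = "ctg1",
    start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L), strand = "+"
  )
  path <- write_gff_file(df)
  genes <- read_gene_coordinates(path, "gX")
  expect_equal(genes$rank[match(c("g1", "g2", "g3"), genes$gene_id)], 0:2)
  # shuffled input gives identical ranks
  path2 <- write_gff_file(df[c(3, 1, 2), ])
  genes2 <- read_gene_coordinates(path2, "gX")
  expect_equal(genes2[order(genes2$gene_id), ], genes[order(genes$gene_id), ])
  # equal starts: deterministic tie-break by gene id
  tie <- tibble::tibble(gene_id = c("zz", "aa"), seq_region = "ctg1",
                        start = c(100L, 100L), end = c(150L, 160L), strand = "+")
  genes3 <- read_gene_coordinates(write_gff_file(tie), "gX")
  expect_equal(genes3$gene_id[order(genes3$rank)], c("aa", "zz"))
})

test_that("gff reader validates coordinates and IDs", {
  bad <- tibble::tibble(gene_id = "g1", seq_region = "c", start = 500L,
                        end = 100L, strand = "+")
  expect_error(read_gene_coordinates(write_gff_file(bad), "gX"))
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "c\tsrc\tgene\t1\t10\t.\t+\t.\tName=noid"), p)
  expect_error(read_gene_coordinates(p, "gX"), class = "panortho_parse_error")
})

test_that("annotation tables parse, validate, and round-trip", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tpfam_ids\tgo_ids",
               "g1\tPF00069\tGO:0004672",
               "g2\t\t"), p)
  ann <- read_annotations(p)
  expect_setequal(ann$term_id[ann$gene_id == "g1"], c("PF00069", "GO:0004672"))
  expect_setequal(attr(ann, "gene_universe"), c("g1", "g2"))
  # empty file -> empty table, no error
  p0 <- tempfile(fileext = ".tsv")
  writeLines("gene_id\tpfam_ids\tgo_ids", p0)
  expect_equal(nrow(read_annotations(p0)), 0L)
  # invalid term id
  pb <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tpfam_ids\tgo_ids", "g1\tPF1\t"), pb)
  expect_error(read_annotations(pb), class = "panortho_parse_error")
  # random 50-gene round trip
  set.seed(42)
  genes <- paste0("g", 1:50)
  tbl <- annotation_table(
    gene_id = rep(genes, each = 2),
    term_id = c(rbind(sprintf("PF%05d", sample(99999, 50)),
                      sprintf("GO:%07d", sample(9999999, 50)))),
    gene_universe = genes
  )
  rt <- tempfile(fileext = ".tsv")
  write_annotations(tbl, rt)
  back <- read_annotations(rt)
  expect_equal(dplyr::arrange(tibble::as_tibble(back), gene_id, term_id),
               dplyr::arrange(tibble::as_tibble(tbl), gene_id, term_id),
               ignore_attr = TRUE)
  expect_setequal(attr(back, "gene_universe"), genes)
})

test_that("domain-hit tables validate their class invariants", {
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    protein_id = c("p1", "p1"), domain_id = c("PF00069", ""),
    domain_class = c("KINASE", "TM"), start = c(1L, 40L), end = c(30L, 60L),
    passes_cutoff = TRUE), p)
  hits <- read_domain_hits(p)
  expect_equal(nrow(hits), 2L)
  write_domain_hits(hits, p)
  expect_equal(as.data.frame(read_domain_hits(p)), as.data.frame(hits))
  bad <- hits
  bad$domain_id[1] <- "PF99999"
  pb <- tempfile(fileext = ".tsv")
  readr::write_tsv(bad, pb)
  expect_error(read_domain_hits(pb), class = "panortho_validation_error")
})

test_that("fasta and newick io round-trip", {
  seqs <- c(s1 = "ATGAAACCC", s2 = "ATGTTTGGA")
  p <- tempfile(fileext = ".fasta")
  write_fasta(seqs, p)
  expect_equal(read_fasta(p), seqs)
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  pt <- tempfile(fileext = ".nwk")
  write_newick(tr, pt)
  back <- read_newick(pt)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$edge.length, tr$edge.length)
})
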
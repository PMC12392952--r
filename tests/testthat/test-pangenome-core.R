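test_that("occupancy counts conserve the gene total", {
  genomes <- three_genomes()
  og <- read_orthogroups(write_og_file(list(
    OG1 = list(gA = c("a1", "a2"), gC = "c1"),
    OG2 = list(gB = "b1")
  ), genomes$genome_id), genomes = genomes)
  occ <- build_occupancy(og)
  M <- occupancy_matrix(occ)
  expect_equal(unname(M["OG1", ]), c(2L, 0L, 1L))
  expect_equal(sum(M), nrow(og))
  # conservation on a 1000-group synthetic table
  sim <- simulate_pangenome(pangenome_sim_config(n_orthogroups = 1000L, seed = 3L))
  expect_equal(sum(occupancy_matrix(build_occupancy(sim$orthogroups))),
               nrow(sim$orthogroups))
})

test_that("pan-gene classification applies the presence-count rule", {
  # N = 10 genomes, softcore fraction 0.9: k=10 core, k=9 softcore, k=5
  # dispensable, k=1 private
  mk_occ <- function(ks) {
    rows <- lapply(seq_along(ks), function(i) {
      tibble::tibble(group_id = sprintf("G%02d", i),
                     genome_id = sprintf("g%02d", seq_len(ks[i])),
                     gene_id = sprintf("G%02d_%02d", i, seq_len(ks[i])))
    })
    og <- dplyr::bind_rows(rows)
    attr(og, "genome_ids") <- sprintf("g%02d", 1:10)
    class(og) <- c("orthogroup_tbl", class(tibble::tibble()))
    build_occupancy(og)
  }
  occ <- mk_occ(c(10, 9, 5, 1))
  cl <- classify_pangene_sets(occ, pan_class_thresholds(0.9, 1))
  got <- setNames(as.character(cl$pan_class), cl$group_id)
  expect_equal(unname(got[c("G01", "G02", "G03", "G04")]),
               c("core", "softcore", "dispensable", "private"))
  # partition property: every group classified exactly once
  expect_equal(nrow(cl), 4L)
  expect_false(anyNA(cl$pan_class))
  # degenerate softcore threshold warns
  expect_warning(classify_pangene_sets(occ, pan_class_thresholds(0.999, 1)),
                 regexp = "softcore")
})

test_that("classification is a partition on simulated input", {
  sim <- small_sim(seed = 21)
  occ <- build_occupancy(sim$orthogroups)
  cl <- classify_pangene_sets(occ, pan_class_thresholds(0.9, 1))
  expect_equal(nrow(cl), length(unique(sim$orthogroups$group_id)))
  s <- pan_class_summary(cl)
  expect_equal(sum(s$n_groups), nrow(cl))
  expect_equal(sum(s$total_genes), nrow(sim$orthogroups))
})

test_that("composition calculator reproduces totals and one-decimal shares", {
  comp <- pan_set_composition(c(core = 12843, softcore = 3735,
                                dispensable = 28790, private = 13698))
  expect_equal(attr(comp, "total"), 59066)
  expect_equal(comp$share_pct, c(21.7, 6.3, 48.7, 23.2))
})

test_that("rarefaction matches exhaustive ordering enumeration", {
  genomes <- three_genomes()
  og <- read_orthogroups(write_og_file(list(
    OG1 = list(gA = "a1", gB = "b1", gC = "c1"),
    OG2 = list(gA = "a2", gB = "b2"),
    OG3 = list(gC = "c3"),
    OG4 = list(gB = "b4")
  ), genomes$genome_id), genomes = genomes)
  occ <- build_occupancy(og)
  cu <- rarefaction_curves(occ, n_permutations = 6L)
  # brute force over all 6 orderings
  P <- occupancy_matrix(occ) > 0
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  pan <- sapply(perms, function(o) sapply(1:3, function(n)
    sum(rowSums(P[, o[1:n], drop = FALSE]) > 0)))
  core <- sapply(perms, function(o) sapply(1:3, function(n)
    sum(rowSums(P[, o[1:n], drop = FALSE]) == n)))
  expect_equal(cu$pan_mean, rowMeans(pan))
  expect_equal(cu$core_mean, rowMeans(core))
  # endpoint consistency
  expect_equal(cu$pan_mean[3], 4)
  expect_equal(cu$core_mean[3], 1)
})

test_that("rarefaction is monotone within every sampled ordering", {
  sim <- small_sim(seed = 31)
  occ <- build_occupancy(sim$orthogroups)
  cu <- rarefaction_curves(occ, n_permutations = 25L, seed = 1L)
  curves <- attr(cu, "curves")
  mono <- curves |>
    dplyr::group_by(perm) |>
    dplyr::summarise(pan_ok = all(diff(pan) >= 0), core_ok = all(diff(core) <= 0))
  expect_true(all(mono$pan_ok))
  expect_true(all(mono$core_ok))
  # nested genomes: pan constant at the superset's group count
  genomes <- three_genomes()
  og <- read_orthogroups(write_og_file(list(
    OG1 = list(gA = "a1", gB = "b1", gC = "c1"),
    OG2 = list(gB = "b2", gC = "c2"),
    OG3 = list(gC = "c3")
  ), genomes$genome_id), genomes = genomes)
  # every genome's groups nest inside gC's? pan(n) varies; instead check
  # all-identical genomes give flat pan
  og2 <- read_orthogroups(write_og_file(list(
    OG1 = list(gA = "a1", gB = "b1", gC = "c1"),
    OG2 = list(gA = "a2", gB = "b2", gC = "c2")
  ), genomes$genome_id), genomes = genomes)
  cu2 <- rarefaction_curves(build_occupancy(og2), 6L)
  expect_equal(cu2$pan_mean, rep(2, 3))
})

test_that("openness fit recovers exact power-law and flags closure", {
  n <- 1:20
  fit <- fit_openness(tibble::tibble(n = n, pan_mean = 100 * n^0.3,
                                     core_mean = 50 + 30 * exp(-n / 4)))
  expect_lt(abs(fit$gamma - 0.3), 1e-6)
  expect_lt(abs(fit$kappa - 100), 1e-4)
  expect_lt(abs(fit$core_asymptote - 50), 1e-3)
  # constant curve: gamma 0, alpha infinite, closed
  fitc <- fit_openness(tibble::tibble(n = 1:10, pan_mean = rep(100, 10),
                                      core_mean = rep(100, 10)))
  expect_equal(fitc$gamma, 0)
  expect_true(is.infinite(fitc$alpha))
  expect_true(fitc$closed_flag)
  # simulated closed pangenome (no private groups, large core)
  cfg <- pangenome_sim_config(
    n_genomes = 12L, group_sizes = c(WILD = 3L, SP = 3L, SLC = 3L, SLL = 3L),
    class_proportions = c(core = 0.8, softcore = 0.1, dispensable = 0.1, private = 0),
    n_orthogroups = 500L, softcore_fraction = 0.9, seed = 8L)
  occ <- build_occupancy(simulate_pangenome(cfg)$orthogroups)
  cu <- rarefaction_curves(occ, 50L, seed = 2L)
  expect_true(fit_openness(cu)$closed_flag)
  # error paths
  expect_error(fit_openness(tibble::tibble(n = 1:3, pan_mean = 1:3, core_mean = 1:3)),
               class = "panortho_validation_error")
  expect_error(fit_openness(tibble::tibble(n = 1:5, pan_mean = c(0, 1:4),
                                           core_mean = rep(1, 5))),
               class = "panortho_validation_error")
  # tidy/glance methods
  expect_equal(nrow(tidy(fit)), 4L)
  expect_true(glance(fitc)$closed)
})
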
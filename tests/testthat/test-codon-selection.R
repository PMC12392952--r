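test_that("F3x4 frequencies are a valid simplex with stop mass removed", {
  aln <- c(a = "ATGATG", b = "ATGATG")
  f <- f3x4_frequencies(aln)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(f["ATG"]), 1)
  set.seed(3)
  aln2 <- c(a = random_codon_seq(50), b = random_codon_seq(50))
  f2 <- f3x4_frequencies(aln2)
  expect_equal(sum(f2), 1, tolerance = 1e-12)
  expect_true(all(f2 >= 0))
  expect_error(f3x4_frequencies(character()), class = "panortho_validation_error")
})

test_that("rate matrix is a scaled reversible generator", {
  pi <- f3x4_frequencies(c(a = random_codon_seq(80)))
  Q <- gy94_rate_matrix(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # detailed balance: the flux matrix pi_i * q_ij is symmetric
  flux <- pi * Q
  expect_lt(max(abs(flux - t(flux))), 1e-14)
  # unit expected substitution rate
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # omega = kappa = 1, uniform pi: all allowed single-step rates equal
  Q1 <- gy94_rate_matrix(1, 1, "uniform")
  off <- Q1[row(Q1) != col(Q1)]
  expect_equal(length(unique(round(off[off > 0], 14))), 1L)
  # multi-nucleotide changes are forbidden
  expect_equal(unname(Q1["AAA", "TTT"]), 0)
})

test_that("transition matrices are stochastic at any branch length", {
  pi <- panortho:::check_codon_freqs("uniform")
  eig <- panortho:::gy94_eigen(2.5, 0.3, pi)
  for (t in c(0, 1e-4, 0.1, 1, 10)) {
    P <- panortho:::transition_matrix(eig, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("pruning equals exhaustive internal-state summation", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  cfg <- codon_sim_config(tree, branch_omega = 0.4, n_codons = 5L, seed = 7L)
  aln <- simulate_codon_alignment(cfg)$alignment
  params <- codon_model_params(2.5, 0.4, "uniform")
  ll <- pruning_loglik(tree, aln, params)
  # brute force: sum over all 61^2 assignments of the two internal nodes
  pi <- panortho:::check_codon_freqs("uniform")
  X <- panortho:::alignment_codon_matrix(aln[tree$tip.label])
  Pe <- panortho:::edge_transition_matrices(tree, rep(0.4, nrow(tree$edge)), 2.5, pi)
  n_tip <- 3L
  bf <- 0
  for (s in seq_len(ncol(X))) {
    tot <- 0
    for (r in 1:61) for (v in 1:61) {
      lik <- pi[r]
      for (k in seq_len(nrow(tree$edge))) {
        from <- tree$edge[k, 1]; to <- tree$edge[k, 2]
        sf <- if (from == n_tip + 1L) r else v
        st <- if (to == n_tip + 1L) r else if (to > n_tip) v else X[to, s]
        lik <- lik * Pe[[k]][sf, st]
      }
      tot <- tot + lik
    }
    bf <- bf + log(tot)
  }
  expect_equal(ll, unname(bf), tolerance = 1e-10)
})

test_that("zero-length limit and re-rooting invariance hold", {
  tree0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  aln <- setNames(rep("ATGAAA", 3), c("A", "B", "C"))
  ll <- pruning_loglik(tree0, aln, codon_model_params(2.5, 0.4, "uniform"))
  expect_equal(ll, 2 * log(1 / 61), tolerance = 1e-10)
  # reversibility: likelihood invariant under re-rooting
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
  cfg <- codon_sim_config(tree, branch_omega = 0.3, n_codons = 30L, seed = 8L)
  aln2 <- simulate_codon_alignment(cfg)$alignment
  params <- codon_model_params(2.5, 0.3, "uniform")
  ll1 <- pruning_loglik(tree, aln2, params)
  rerooted <- ape::root(ape::unroot(tree), outgroup = "C", resolve.root = TRUE)
  ll2 <- pruning_loglik(rerooted, aln2, params)
  expect_equal(ll1, ll2, tolerance = 1e-8)
  expect_error(pruning_loglik(tree, aln2[c("A", "B", "C")], params),
               class = "panortho_validation_error")
})

test_that("branch-model fits recover omega and respect nesting", {
  tree <- six_taxon_tree()
  fg <- c("A", "B")
  # under the null, foreground and background estimates agree
  ok <- 0L
  for (i in 1:10) {
    cfg <- codon_sim_config(tree, branch_omega = 0.2, n_codons = 500L,
                            seed = 40L + i)
    aln <- simulate_codon_alignment(cfg)$alignment
    f <- fit_branch_models(tree, aln, fg, fit_h2 = FALSE)
    if (abs(f$H1$omega["foreground"] - f$H1$omega["background"]) < 0.15) ok <- ok + 1L
    expect_gte(f$H1$loglik, f$H0$loglik - 1e-6)
  }
  expect_gte(ok, 8L)
  # under the alternative, the foreground estimate exceeds the background
  cfg <- codon_sim_config(tree, branch_omega = list(foreground = fg, fg = 1.5, bg = 0.2),
                          n_codons = 500L, seed = 99L)
  aln <- simulate_codon_alignment(cfg)$alignment
  f <- fit_branch_models(tree, aln, fg, fit_h2 = TRUE)
  expect_gt(f$H1$omega["foreground"], f$H1$omega["background"])
  expect_gte(f$H2$loglik, f$H1$loglik - 1e-6)
  expect_gte(f$H1$loglik, f$H0$loglik - 1e-6)
  # foreground required for H1
  expect_error(fit_hypothesis(tree, aln, "H1"), class = "panortho_config_error")
  # tidy/glance methods
  expect_true(all(c("foreground", "background") %in% tidy(f$H1)$term))
  expect_equal(glance(f$H0)$hypothesis, "H0")
})

test_that("decision rules implement the two-test LRT cascade", {
  mk_fit <- function(hyp, ll, omega, npar = 1L) {
    structure(list(hypothesis = hyp, loglik = ll, omega = omega, kappa = 2.5,
                   scale = 1, npar = npar, convergence = TRUE),
              class = "codon_fit")
  }
  base <- function(l0, l1, l2, wfg, wbg, lbs0 = NULL, lbs1 = NULL) {
    f <- list(
      H0 = mk_fit("H0", l0, c(all = wbg)),
      H1 = mk_fit("H1", l1, c(foreground = wfg, background = wbg), 2L),
      H2 = mk_fit("H2", l2, setNames(rep(wbg, 9), paste0("edge", 1:9)), 9L))
    if (!is.null(lbs0)) {
      f$BS_null <- mk_fit("BS_null", lbs0, c(w2 = 1), 3L)
      f$BS_alt <- mk_fit("BS_alt", lbs1, c(w2 = 3), 4L)
    }
    f
  }
  fits <- list(
    # strong H1 gain, negligible H2 gain, omega_fg > omega_bg: rapid
    rapid = base(-1000, -985, -984.5, 1.5, 0.2),
    # 2*dloglik = 0: p = 1, no call
    null = base(-1000, -1000, -1000, 0.2, 0.2),
    # significant H1 but H2 still much better: not rapid
    h2wins = base(-1000, -985, -940, 1.5, 0.2),
    # H1 gain with foreground omega below background: not rapid
    slower = base(-1000, -985, -984.5, 0.1, 0.8),
    # branch-site signal only
    possel = base(-1000, -999.9, -999.8, 0.2, 0.2, lbs0 = -990, lbs1 = -975))
  calls <- call_rapid_and_positive(fits, alpha = 0.01)
  dec <- setNames(calls$decision, calls$orthogroup)
  expect_equal(unname(dec["rapid"]), "rapidly_evolving")
  expect_equal(unname(dec["null"]), "none")
  expect_equal(unname(dec["h2wins"]), "none")
  expect_equal(unname(dec["slower"]), "none")
  expect_equal(unname(dec["possel"]), "positively_selected")
  expect_equal(calls$p_h1_h0[calls$orthogroup == "null"], 1)
  # missing-fit orthogroups are skipped with a warning
  expect_warning(call_rapid_and_positive(c(fits, list(broken = list(H0 = fits$null$H0)))),
                 regexp = "broken")
})

test_that("branch-site fits detect simulated positive selection", {
  tree <- six_taxon_tree()
  fg <- c("A", "B")
  cfg <- codon_sim_config(tree, branch_omega = list(foreground = fg, fg = 4, bg = 0.2),
                          n_codons = 300L, seed = 77L)
  aln <- simulate_codon_alignment(cfg)$alignment
  bs <- fit_branch_site(tree, aln, fg)
  expect_gte(bs$alt$loglik, bs$null$loglik)
  lrt <- 2 * (bs$alt$loglik - bs$null$loglik)
  expect_gt(lrt, qchisq(0.99, 1))
  expect_gt(bs$alt$omega["w2"], 1)
  # and the null fit on null data shows no signal
  cfg0 <- codon_sim_config(tree, branch_omega = 0.2, n_codons = 300L, seed = 78L)
  aln0 <- simulate_codon_alignment(cfg0)$alignment
  bs0 <- fit_branch_site(tree, aln0, fg)
  lrt0 <- 2 * (bs0$alt$loglik - bs0$null$loglik)
  expect_lt(lrt0, qchisq(0.999, 1))
})
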
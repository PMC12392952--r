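#' Configuration for codon-alignment simulation
#'
#' Defines the tree and Goldman-Yang parameters under which codons are
#' evolved. Branch-specific omegas may be given as a scalar (all branches),
#' as `list(foreground = <tips>, fg = <omega>, bg = <omega>)` (branches whose
#' descendant tips all lie in `foreground` get `fg`), or as a numeric vector
#' with one entry per row of `tree$edge` (an entry for every branch is then
#' required).
#'
#' @param tree Newick string or `phylo` with branch lengths (>= 2 tips).
#' @param branch_omega Scalar, foreground list, or per-edge numeric vector.
#' @param kappa Transition/transversion ratio (default 2.5).
#' @param codon_freqs Length-61 simplex or `"uniform"`.
#' @param n_codons Number of codon sites to simulate.
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return A list of class `codon_sim_config`.
#' @export
codon_sim_config <- function(tree, branch_omega = 0.2, kappa = 2.5,
                             codon_freqs = "uniform", n_codons = 300L,
                             seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop_config("tree must be a phylo or newick string")
  if (length(tree$tip.label) < 2L) stop_config("tree must have >= 2 tips")
  if (is.null(tree$edge.length)) stop_config("tree must carry branch lengths")
  if (!is.numeric(kappa) || kappa <= 0) stop_config("kappa must be > 0")
  n_codons <- check_count(n_codons, "n_codons", min = 1L)
  edge_omega <- resolve_branch_omega(tree, branch_omega)
  if (any(edge_omega < 0)) stop_config("omega must be >= 0")
  structure(list(tree = tree, edge_omega = edge_omega, kappa = kappa,
                 codon_freqs = check_codon_freqs(codon_freqs),
                 n_codons = n_codons, seed = seed),
            class = "codon_sim_config")
}

resolve_branch_omega <- function(tree, branch_omega) {
  n_edge <- nrow(tree$edge)
  if (is.list(branch_omega)) {
    need <- c("foreground", "fg", "bg")
    if (!all(need %in% names(branch_omega))) {
      stop_config("list branch_omega needs elements foreground, fg, bg")
    }
    fg_edges <- foreground_edges(tree, branch_omega$foreground)
    out <- rep(branch_omega$bg, n_edge)
    out[fg_edges] <- branch_omega$fg
    return(out)
  }
  if (length(branch_omega) == 1L) return(rep(branch_omega, n_edge))
  if (length(branch_omega) != n_edge) {
    stop_config(sprintf("branch_omega has %d values but the tree has %d branches",
                        length(branch_omega), n_edge))
  }
  as.numeric(branch_omega)
}

#' Identify foreground branches from a tip set
#'
#' A branch is foreground when every tip descending from it belongs to the
#' given tip set (so a full foreground clade includes its stem branch).
#'
#' @param tree A `phylo`.
#' @param foreground_tips Character vector of tip labels.
#' @return Integer indices into rows of `tree$edge`.
#' @export
foreground_edges <- function(tree, foreground_tips) {
  miss <- setdiff(foreground_tips, tree$tip.label)
  if (length(miss)) {
    stop_config(paste0("foreground tip(s) not in tree: ", paste(miss, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, desc))
  }
  which(vapply(tree$edge[, 2L], function(node) {
    all(desc(node) %in% foreground_tips)
  }, logical(1L)))
}

#' Simulate a codon alignment under branch-specific selection
#'
#' Evolves codon sites along the tree under the Goldman-Yang model: the root
#' state is drawn from the equilibrium frequencies and each branch applies
#' the exact transition matrix `exp(Q_omega * t)` of its branch class. With
#' `omega = 0` on every branch no nonsynonymous change can occur; with all
#' branch lengths zero all sequences are identical.
#'
#' @param config A [codon_sim_config()].
#' @return A list with `alignment` (named character vector of codon
#'   sequences, one per tip) and `params` (the true simulation parameters).
#' @export
simulate_codon_alignment <- function(config) {
  if (!inherits(config, "codon_sim_config")) stop_config("config must be a codon_sim_config")
  tab <- codon_tables()
  tree <- config$tree
  pi <- config$codon_freqs
  P_edge <- edge_transition_matrices(tree, config$edge_omega, config$kappa, pi)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  with_seed(config$seed, {
    states <- matrix(NA_integer_, n_node, config$n_codons)
    root <- n_tip + 1L
    states[root, ] <- sample.int(length(pi), config$n_codons, replace = TRUE, prob = pi)
    # preorder: parents before children
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(pre$edge))) {
      parent <- pre$edge[k, 1L]
      child <- pre$edge[k, 2L]
      i <- match(paste(parent, child), paste(tree$edge[, 1L], tree$edge[, 2L]))
      P <- P_edge[[i]]
      par_states <- states[parent, ]
      child_states <- integer(length(par_states))
      for (s in unique(par_states)) {
        at <- which(par_states == s)
        child_states[at] <- sample.int(ncol(P), length(at), replace = TRUE, prob = P[s, ])
      }
      states[child, ] <- child_states
    }
    aln <- apply(states[seq_len(n_tip), , drop = FALSE], 1L, function(v) {
      paste(tab$codons[v], collapse = "")
    })
    list(alignment = setNames(aln, tree$tip.label),
         params = list(tree = tree, edge_omega = config$edge_omega,
                       kappa = config$kappa, codon_freqs = pi))
  })
}
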
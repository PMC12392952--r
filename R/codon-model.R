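# Goldman-Yang style codon substitution model over the 61 sense codons of the
# universal genetic code, with F3x4 frequencies and Felsenstein pruning.

codon_env <- new.env(parent = emptyenv())

# Memoized lookup tables: the 61 sense codons, their amino acids, and the
# single-nucleotide neighbour structure (position, transition vs transversion,
# synonymous vs nonsynonymous).
codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  nt <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1], 1L, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  stops <- all64[aa == "*"]
  codons <- all64[aa != "*"]
  aa61 <- aa[aa != "*"]
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  # pairwise single-change structure
  pos_mat <- matrix(0L, n, n)
  ts_mat <- matrix(FALSE, n, n)
  syn_mat <- matrix(FALSE, n, n)
  split3 <- do.call(rbind, strsplit(codons, ""))
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffs <- which(split3[i, ] != split3[j, ])
      if (length(diffs) == 1L) {
        pos_mat[i, j] <- diffs
        ts_mat[i, j] <- is_ts(split3[i, diffs], split3[j, diffs])
        syn_mat[i, j] <- aa61[i] == aa61[j]
      }
    }
  }
  codon_env$tab <- list(codons = codons, aa = setNames(aa61, codons), stops = stops,
                        idx = idx, pos = pos_mat, ts = ts_mat, syn = syn_mat,
                        split3 = split3, nt = nt)
  codon_env$tab
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  if (nchar(seq) == 0L) return(character())
  if (nchar(seq) %% 3L != 0L) {
    stop_validate(sprintf("sequence length %d is not a multiple of 3", nchar(seq)))
  }
  substring(seq, seq(1L, nchar(seq), by = 3L), seq(3L, nchar(seq), by = 3L))
}

#' Empirical F3x4 codon frequencies
#'
#' Estimates codon frequencies as the product of the per-codon-position
#' nucleotide frequencies observed in the alignment (the F3x4 scheme), with
#' stop-codon mass removed and the 61 sense-codon frequencies renormalized to
#' sum to one.
#'
#' @param alignment Named character vector of aligned coding sequences; codon
#'   columns containing a gap in any sequence are ignored.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
f3x4_frequencies <- function(alignment) {
  if (length(alignment) == 0L || all(nchar(alignment) == 0L)) {
    stop_validate("empty alignment")
  }
  tab <- codon_tables()
  mats <- lapply(alignment, function(s) do.call(rbind, strsplit(split_codons(s), "")))
  keep <- Reduce(`&`, lapply(mats, function(m) rowSums(m == "-") == 0L))
  counts <- matrix(0, nrow = 3L, ncol = 4L, dimnames = list(NULL, tab$nt))
  for (m in mats) {
    mm <- m[keep, , drop = FALSE]
    for (p in 1:3) {
      t <- table(factor(mm[, p], levels = tab$nt))
      counts[p, ] <- counts[p, ] + as.numeric(t)
    }
  }
  if (sum(counts) == 0) stop_validate("alignment has no gap-free codon columns")
  pos_freq <- counts / rowSums(counts)
  f <- pos_freq[1L, tab$split3[, 1L]] * pos_freq[2L, tab$split3[, 2L]] *
    pos_freq[3L, tab$split3[, 3L]]
  f <- f / sum(f)
  setNames(f, tab$codons)
}

uniform_codon_freqs <- function() {
  tab <- codon_tables()
  setNames(rep(1 / length(tab$codons), length(tab$codons)), tab$codons)
}

check_codon_freqs <- function(codon_freqs) {
  tab <- codon_tables()
  if (is.character(codon_freqs) && length(codon_freqs) == 1L && codon_freqs == "uniform") {
    return(uniform_codon_freqs())
  }
  if (length(codon_freqs) != length(tab$codons)) {
    stop_config("codon_freqs must have length 61 (sense codons)")
  }
  if (abs(sum(codon_freqs) - 1) > 1e-6 || any(codon_freqs < 0)) {
    stop_config("codon_freqs must be a simplex (nonnegative, summing to 1)")
  }
  if (!is.null(names(codon_freqs))) codon_freqs <- codon_freqs[tab$codons]
  setNames(as.numeric(codon_freqs) / sum(codon_freqs), tab$codons)
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 reversible generator with off-diagonal rate
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]` for single-nucleotide
#' changes and zero otherwise, scaled so that the expected number of
#' substitutions per unit branch length equals one.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freqs Length-61 simplex or `"uniform"`.
#' @return A 61x61 matrix with rows summing to zero.
#' @export
gy94_rate_matrix <- function(kappa, omega, codon_freqs = "uniform") {
  if (!is.numeric(kappa) || kappa <= 0) stop_config("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop_config("omega must be >= 0")
  tab <- codon_tables()
  pi <- check_codon_freqs(codon_freqs)
  single <- tab$pos > 0L
  Q <- matrix(0, length(pi), length(pi), dimnames = list(tab$codons, tab$codons))
  rate <- matrix(pi, nrow = length(pi), ncol = length(pi), byrow = TRUE)
  rate[tab$ts] <- rate[tab$ts] * kappa
  rate[!tab$syn] <- rate[!tab$syn] * omega
  Q[single] <- rate[single]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  Q
}

# Symmetrized eigendecomposition of a reversible generator; P(t) = A e^{Lt} B.
gy94_eigen <- function(kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  s <- sqrt(pi)
  S <- Q * (s %o% (1 / s))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  # Q = D^{-1} V L V' D with D = diag(sqrt(pi)), so P(t) = A exp(Lt) B
  list(A = e$vectors / s, B = t(e$vectors * s), lambda = e$values)
}

transition_matrix <- function(eig, t) {
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  P
}

# Convert a codon alignment (named character vector) to an integer matrix of
# codon indices (tips x sites), NA for codons containing gaps/ambiguity.
alignment_codon_matrix <- function(alignment) {
  tab <- codon_tables()
  rows <- lapply(alignment, function(s) {
    cod <- split_codons(s)
    bad_stop <- which(cod %in% tab$stops)
    if (length(bad_stop)) {
      stop_validate(sprintf("stop codon at codon position %d", bad_stop[1L]))
    }
    unname(tab$idx[cod])
  })
  L <- unique(lengths(rows))
  if (length(L) != 1L) stop_validate("aligned sequences differ in codon length")
  do.call(rbind, rows)
}

compress_patterns <- function(X) {
  key <- apply(X, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(X = X[, u, drop = FALSE], weights = as.numeric(table(key)[key[u]]))
}

# Per-pattern site likelihoods by Felsenstein pruning.
# tree: rooted/unrooted ape phylo; X: tips x patterns integer matrix (rows in
# tree tip order); P_edge: list of transition matrices per tree$edge row.
prune_site_likelihoods <- function(tree, X, P_edge, pi) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  npat <- ncol(X)
  ns <- length(pi)
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  partial <- vector("list", n_node)
  for (tip in seq_len(n_tip)) {
    M <- matrix(0, ns, npat)
    obs <- X[tip, ]
    known <- !is.na(obs)
    M[cbind(obs[known], which(known))] <- 1
    if (any(!known)) M[, which(!known)] <- 1
    partial[[tip]] <- M
  }
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1L]
    child <- tr$edge[k, 2L]
    P <- P_edge[[ord[k]]]
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
  }
  root <- n_tip + 1L
  as.numeric(pi %*% partial[[root]])
}

# Edge transition matrices for a set of per-edge omegas (vector along
# tree$edge rows), a global branch-length scale, kappa and frequencies.
edge_transition_matrices <- function(tree, edge_omega, kappa, pi, scale = 1) {
  lens <- tree$edge.length * scale
  uo <- unique(edge_omega)
  eigs <- lapply(uo, function(w) gy94_eigen(kappa, w, pi))
  names(eigs) <- as.character(uo)
  lapply(seq_along(lens), function(i) {
    transition_matrix(eigs[[as.character(edge_omega[i])]], lens[i])
  })
}

#' Codon model parameters
#'
#' Bundles the parameters of the codon substitution model used by
#' [pruning_loglik()]: `kappa`, per-edge `omega` (a scalar applies to every
#' branch), codon frequencies and a global branch-length scale.
#'
#' @param kappa Transition/transversion ratio.
#' @param omega Scalar omega, or a numeric vector with one entry per row of
#'   `tree$edge`.
#' @param codon_freqs Length-61 simplex or `"uniform"`.
#' @param scale Multiplier applied to all branch lengths.
#' @return A list of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2.5, omega = 0.2, codon_freqs = "uniform",
                               scale = 1) {
  if (any(omega < 0)) stop_config("omega must be >= 0")
  structure(list(kappa = kappa, omega = omega,
                 codon_freqs = check_codon_freqs(codon_freqs), scale = scale),
            class = "codon_model_params")
}

#' Codon-alignment log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a tree under the
#' Goldman-Yang model, summing per-site log-likelihoods over compressed site
#' patterns. With all branch lengths zero and identical sequences this
#' reduces to the sum of log equilibrium frequencies of the observed codons.
#'
#' @param tree An `ape::phylo` with branch lengths; tip labels must match the
#'   alignment names.
#' @param alignment Named character vector of gap-free codon sequences (codons
#'   containing gaps are treated as missing data).
#' @param params A [codon_model_params()] object.
#' @return The log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, alignment, params = codon_model_params()) {
  if (!inherits(params, "codon_model_params")) stop_config("params must be codon_model_params()")
  miss <- setdiff(tree$tip.label, names(alignment))
  if (length(miss)) {
    stop_validate(paste0("alignment missing sequences for tip(s): ",
                         paste(miss, collapse = ", ")))
  }
  X <- alignment_codon_matrix(alignment[tree$tip.label])
  cp <- compress_patterns(X)
  omega <- params$omega
  if (length(omega) == 1L) omega <- rep(omega, nrow(tree$edge))
  if (length(omega) != nrow(tree$edge)) {
    stop_config("omega must be scalar or one value per edge")
  }
  pi <- params$codon_freqs
  P_edge <- edge_transition_matrices(tree, omega, params$kappa, pi, params$scale)
  lik <- prune_site_likelihoods(tree, cp$X, P_edge, pi)
  sum(cp$weights * log(lik))
}
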
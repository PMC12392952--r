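# Maximum-likelihood fitting of branch and branch-site codon models, and the
# likelihood-ratio decision rules for rapidly evolving and positively
# selected orthogroups.

HYPOTHESES <- c("H0", "H1", "H2", "BS_null", "BS_alt")

# Shared precomputation for one (tree, alignment) pair.
codon_fit_data <- function(tree, alignment, codon_freqs = "F3x4") {
  miss <- setdiff(tree$tip.label, names(alignment))
  if (length(miss)) {
    stop_validate(paste0("alignment missing sequences for tip(s): ",
                         paste(miss, collapse = ", ")))
  }
  pi <- if (identical(codon_freqs, "F3x4")) {
    f3x4_frequencies(alignment[tree$tip.label])
  } else {
    check_codon_freqs(codon_freqs)
  }
  X <- alignment_codon_matrix(alignment[tree$tip.label])
  cp <- compress_patterns(X)
  list(tree = tree, X = cp$X, weights = cp$weights, pi = pi)
}

# log-likelihood for per-edge omega vector at given kappa/scale
fit_loglik <- function(dat, edge_omega, kappa, scale) {
  P_edge <- edge_transition_matrices(dat$tree, edge_omega, kappa, dat$pi, scale)
  lik <- prune_site_likelihoods(dat$tree, dat$X, P_edge, dat$pi)
  if (any(lik <= 0)) return(-Inf)
  sum(dat$weights * log(lik))
}

# branch-site mixture log-likelihood; p = c(p0, p1), site classes
# 0: (bg w0, fg w0), 1: (bg 1, fg 1), 2a: (bg w0, fg w2), 2b: (bg 1, fg w2)
bs_loglik <- function(dat, fg_edges, w0, w2, p0, p1, kappa, scale) {
  n_edge <- nrow(dat$tree$edge)
  omega_sets <- list(
    rep(w0, n_edge),
    rep(1, n_edge),
    {v <- rep(w0, n_edge); v[fg_edges] <- w2; v},
    {v <- rep(1, n_edge); v[fg_edges] <- w2; v}
  )
  p2 <- max(0, 1 - p0 - p1)
  denom <- p0 + p1
  wts <- c(p0, p1,
           if (denom > 0) p2 * p0 / denom else p2 / 2,
           if (denom > 0) p2 * p1 / denom else p2 / 2)
  lik <- 0
  for (k in seq_along(omega_sets)) {
    if (wts[k] == 0) next
    P_edge <- edge_transition_matrices(dat$tree, omega_sets[[k]], kappa, dat$pi, scale)
    lik <- lik + wts[k] * prune_site_likelihoods(dat$tree, dat$X, P_edge, dat$pi)
  }
  if (any(lik <= 0)) return(-Inf)
  sum(dat$weights * log(lik))
}

OMEGA_LO <- 1e-4
OMEGA_HI <- 50

#' Fit one codon-model hypothesis by maximum likelihood
#'
#' Fits the branch-model hypotheses `H0` (a single omega on every branch),
#' `H1` (one foreground omega, one shared background omega), `H2` (a free
#' omega on every branch), or the branch-site pair `BS_null` / `BS_alt`
#' (four-site-class mixture; the foreground site-class omega is fixed at 1
#' under the null and free in `[1, 50]`, initialized at 1.5, under the
#' alternative). Omegas are optimized by bounded quasi-Newton search with
#' multiple starts; kappa defaults to 2.5 and branch lengths are taken from
#' the input tree, optionally rescaled by a single factor estimated under
#' `H0` and then held fixed across hypotheses.
#'
#' @param tree A `phylo` with branch lengths.
#' @param alignment Named character vector of codon sequences.
#' @param hypothesis One of `"H0"`, `"H1"`, `"H2"`, `"BS_null"`, `"BS_alt"`.
#' @param foreground Character vector of foreground tip labels (required for
#'   `H1` and the branch-site hypotheses).
#' @param kappa Transition/transversion ratio (fixed; default 2.5).
#' @param init_omega Initial omega (default 0.2).
#' @param starts Additional omega starting values for the multi-start search.
#' @param codon_freqs `"F3x4"` (estimated from the alignment) or a supplied
#'   simplex / `"uniform"`.
#' @param scale Branch-length scale factor; `NULL` (only meaningful for
#'   `H0`) estimates it jointly with omega.
#' @return An object of class `codon_fit` with elements `hypothesis`,
#'   `loglik`, `omega` (named estimates), `kappa`, `scale`, `npar`,
#'   `convergence`.
#' @export
fit_hypothesis <- function(tree, alignment, hypothesis = c("H0", "H1", "H2", "BS_null", "BS_alt"),
                           foreground = NULL, kappa = 2.5, init_omega = 0.2,
                           starts = c(0.2, 1, 2), codon_freqs = "F3x4",
                           scale = 1) {
  hypothesis <- match.arg(hypothesis)
  dat <- codon_fit_data(tree, alignment, codon_freqs)
  fit_hypothesis_impl(dat, hypothesis, foreground, kappa, init_omega, starts, scale)
}

fit_hypothesis_impl <- function(dat, hypothesis, foreground, kappa, init_omega,
                                starts, scale) {
  tree <- dat$tree
  n_edge <- nrow(tree$edge)
  fg_edges <- integer()
  if (hypothesis %in% c("H1", "BS_null", "BS_alt")) {
    if (is.null(foreground) || !length(foreground)) {
      stop_config(sprintf("%s requires a nonempty foreground tip set", hypothesis))
    }
    fg_edges <- foreground_edges(tree, foreground)
    if (!length(fg_edges)) stop_config("foreground tips define no foreground branch")
  }
  starts <- unique(c(init_omega, starts))
  est_scale <- is.null(scale)

  run_optim <- function(par0, fn, lower, upper) {
    optim(par0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(fnscale = -1, factr = 1e9, maxit = 200L))
  }

  if (hypothesis == "H0" && !est_scale) {
    # one-dimensional: golden-section/parabolic search on log-omega
    opt <- optimize(function(lw) fit_loglik(dat, rep(exp(lw), n_edge), kappa, scale),
                    interval = c(log(OMEGA_LO), log(OMEGA_HI)), maximum = TRUE,
                    tol = 1e-7)
    return(structure(list(hypothesis = "H0", loglik = opt$objective,
                          omega = c(all = exp(opt$maximum)), kappa = kappa,
                          scale = scale, foreground = foreground, npar = 1L,
                          convergence = TRUE),
                     class = "codon_fit"))
  }

  if (hypothesis %in% c("H0", "H1", "H2")) {
    n_w <- switch(hypothesis, H0 = 1L, H1 = 2L, H2 = n_edge)
    omega_of <- function(w) {
      switch(hypothesis,
             H0 = rep(w[1L], n_edge),
             H1 = {v <- rep(w[2L], n_edge); v[fg_edges] <- w[1L]; v},
             H2 = w)
    }
    fn <- function(par) {
      w <- exp(par[seq_len(n_w)])
      sc <- if (est_scale) exp(par[n_w + 1L]) else scale
      fit_loglik(dat, omega_of(w), kappa, sc)
    }
    lower <- rep(log(OMEGA_LO), n_w + est_scale)
    upper <- c(rep(log(OMEGA_HI), n_w), if (est_scale) log(100))
    if (est_scale) lower[n_w + 1L] <- log(1e-4)
    best <- NULL
    for (s in starts) {
      par0 <- c(rep(log(pmin(pmax(s, OMEGA_LO), OMEGA_HI)), n_w), if (est_scale) 0)
      opt <- run_optim(par0, fn, lower, upper)
      if (is.null(best) || opt$value > best$value) best <- opt
    }
    w_hat <- exp(best$par[seq_len(n_w)])
    sc_hat <- if (est_scale) exp(best$par[n_w + 1L]) else scale
    omega <- switch(hypothesis,
                    H0 = c(all = w_hat[1L]),
                    H1 = c(foreground = w_hat[1L], background = w_hat[2L]),
                    H2 = setNames(w_hat, paste0("edge", seq_len(n_edge))))
    npar <- n_w + est_scale
    return(structure(list(hypothesis = hypothesis, loglik = best$value,
                          omega = omega, kappa = kappa, scale = sc_hat,
                          foreground = foreground, npar = npar,
                          convergence = best$convergence == 0L),
                     class = "codon_fit"))
  }

  # branch-site mixture: free parameters p0, p1 (stick-breaking), w0 in (0,1),
  # and w2 (fixed at 1 under the null, free in [1, 50] under the alternative)
  alt <- hypothesis == "BS_alt"
  fn <- function(par) {
    q0 <- plogis(par[1L]); q1 <- plogis(par[2L])
    p0 <- q0; p1 <- (1 - q0) * q1
    w0 <- plogis(par[3L])
    w2 <- if (alt) 1 + exp(par[4L]) else 1
    bs_loglik(dat, fg_edges, w0, w2, p0, p1, kappa, scale %||% 1)
  }
  npar <- if (alt) 4L else 3L
  lower <- c(-7, -7, log(OMEGA_LO) , if (alt) log(1e-6))
  upper <- c(7, 7, 7, if (alt) log(OMEGA_HI - 1))
  best <- NULL
  for (w2s in if (alt) c(1.5, 3) else 1) {
    par0 <- c(stats::qlogis(0.7), stats::qlogis(0.5), stats::qlogis(0.2),
              if (alt) log(w2s - 1))
    opt <- run_optim(par0, fn, lower, upper)
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  q0 <- plogis(best$par[1L]); q1 <- plogis(best$par[2L])
  omega <- c(w0 = plogis(best$par[3L]), w1 = 1,
             w2 = if (alt) 1 + exp(best$par[4L]) else 1,
             p0 = q0, p1 = (1 - q0) * q1)
  structure(list(hypothesis = hypothesis, loglik = best$value, omega = omega,
                 kappa = kappa, scale = scale %||% 1, foreground = foreground,
                 npar = npar, convergence = best$convergence == 0L),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("<codon_fit %s> loglik = %.4f, kappa = %.3g\n",
              x$hypothesis, x$loglik, x$kappa))
  print(round(x$omega, 4))
  invisible(x)
}

#' @rdname fit_hypothesis
#' @param ... Passed on to [fit_hypothesis()].
#' @return `fit_branch_models()`: a list with elements `H0`, `H1`, `H2`
#'   (fit `H2` only when `fit_h2 = TRUE`); the branch-length scale is
#'   estimated under `H0` and fixed for the other hypotheses, and `H1`/`H2`
#'   start from the `H0` optimum so the nesting
#'   `loglik(H2) >= loglik(H1) >= loglik(H0)` holds at convergence.
#' @param fit_h2 Fit the all-branches-free hypothesis as well.
#' @param estimate_scale Estimate a global branch-length scale under `H0`.
#' @export
fit_branch_models <- function(tree, alignment, foreground, kappa = 2.5,
                              init_omega = 0.2, starts = c(0.2, 1, 2),
                              codon_freqs = "F3x4", fit_h2 = TRUE,
                              estimate_scale = FALSE) {
  dat <- codon_fit_data(tree, alignment, codon_freqs)
  h0 <- fit_hypothesis_impl(dat, "H0", NULL, kappa, init_omega, starts,
                            scale = if (estimate_scale) NULL else 1)
  sc <- h0$scale
  w0 <- unname(h0$omega[1L])
  # warm-start H1 at the H0 optimum plus one dispersed start
  h1 <- fit_hypothesis_impl(dat, "H1", foreground, kappa, w0,
                            unique(c(w0, max(starts))), scale = sc)
  out <- list(H0 = h0, H1 = h1)
  if (fit_h2) {
    w_init <- unname(h1$omega["background"])
    out$H2 <- fit_hypothesis_impl(dat, "H2", NULL, kappa, w_init,
                                  unique(c(w_init, init_omega)), scale = sc)
    # guarantee nesting numerically: H2 must not fall below H1
    if (out$H2$loglik < h1$loglik) {
      v <- rep(unname(h1$omega["background"]), nrow(dat$tree$edge))
      v[foreground_edges(dat$tree, foreground)] <- unname(h1$omega["foreground"])
      ll <- fit_loglik(dat, v, kappa, sc)
      if (ll > out$H2$loglik) {
        out$H2$loglik <- ll
        out$H2$omega <- setNames(v, paste0("edge", seq_along(v)))
      }
    }
  }
  out
}

#' @rdname fit_hypothesis
#' @return `fit_branch_site()`: list with elements `null` and `alt`.
#' @export
fit_branch_site <- function(tree, alignment, foreground, kappa = 2.5,
                            codon_freqs = "F3x4") {
  dat <- codon_fit_data(tree, alignment, codon_freqs)
  null <- fit_hypothesis_impl(dat, "BS_null", foreground, kappa, 0.2, 0.2, scale = 1)
  alt <- fit_hypothesis_impl(dat, "BS_alt", foreground, kappa, 0.2, 0.2, scale = 1)
  if (alt$loglik < null$loglik) {
    # the null is nested in the alternative at w2 = 1
    alt$loglik <- null$loglik
    alt$omega <- null$omega
  }
  list(null = null, alt = alt)
}

#' Call rapidly evolving and positively selected orthogroups
#'
#' Applies the likelihood-ratio decision rules to per-orthogroup model fits.
#' An orthogroup is called rapidly evolving when the `H1` vs `H0` test is
#' significant after Benjamini-Hochberg FDR correction across orthogroups
#' (chi-square, df 1), the `H2` vs `H1` test is *not* significant
#' (chi-square, df `n_branches - 2`), and the foreground omega exceeds the
#' background omega. It is called positively selected when the branch-site
#' alternative beats its null after FDR correction (chi-square, df 1). The
#' two test families are corrected separately.
#'
#' @param fits A named list; each element is a per-orthogroup list with
#'   components `H0`, `H1` and optionally `H2`, `BS_null`, `BS_alt`
#'   ([fit_branch_models()] / [fit_branch_site()] output, with the
#'   branch-site pair supplied as `BS_null`/`BS_alt`).
#' @param alpha Adjusted-p threshold for both families (default 0.01).
#' @return A tibble of class `lrt_tbl`: one row per orthogroup with
#'   log-likelihoods, omega estimates, LRT statistics, raw and FDR-adjusted
#'   p-values and the `decision` (`rapidly_evolving`, `positively_selected`,
#'   `both` or `none`). Orthogroups missing a required fit are dropped with
#'   a warning naming them.
#' @export
call_rapid_and_positive <- function(fits, alpha = 0.01) {
  if (is.null(names(fits))) names(fits) <- paste0("OG", seq_along(fits))
  ok <- vapply(fits, function(f) all(c("H0", "H1") %in% names(f)), logical(1L))
  if (any(!ok)) {
    warn(paste0("skipping orthogroup(s) without H0/H1 fits: ",
                paste(names(fits)[!ok], collapse = ", ")))
    fits <- fits[ok]
  }
  rows <- imap(fits, function(f, id) {
    n_branch <- if (!is.null(f$H2)) length(f$H2$omega) else NA_integer_
    lrt10 <- max(0, 2 * (f$H1$loglik - f$H0$loglik))
    p10 <- pchisq(lrt10, df = 1L, lower.tail = FALSE)
    if (!is.null(f$H2)) {
      lrt21 <- max(0, 2 * (f$H2$loglik - f$H1$loglik))
      df21 <- max(1L, n_branch - 2L)
      p21 <- pchisq(lrt21, df = df21, lower.tail = FALSE)
    } else {
      lrt21 <- NA_real_; p21 <- NA_real_
    }
    if (!is.null(f$BS_null) && !is.null(f$BS_alt)) {
      lrt_bs <- max(0, 2 * (f$BS_alt$loglik - f$BS_null$loglik))
      p_bs <- pchisq(lrt_bs, df = 1L, lower.tail = FALSE)
    } else {
      lrt_bs <- NA_real_; p_bs <- NA_real_
    }
    tibble(orthogroup = id,
           loglik_h0 = f$H0$loglik, loglik_h1 = f$H1$loglik,
           loglik_h2 = if (!is.null(f$H2)) f$H2$loglik else NA_real_,
           omega_fg = unname(f$H1$omega["foreground"]),
           omega_bg = unname(f$H1$omega["background"]),
           lrt_h1_h0 = lrt10, p_h1_h0 = p10,
           lrt_h2_h1 = lrt21, p_h2_h1 = p21,
           lrt_bs = lrt_bs, p_bs = p_bs)
  })
  out <- list_rbind(rows)
  out$p_adj_h1_h0 <- p.adjust(out$p_h1_h0, method = "BH")
  out$p_adj_bs <- rep(NA_real_, nrow(out))
  has_bs <- !is.na(out$p_bs)
  out$p_adj_bs[has_bs] <- p.adjust(out$p_bs[has_bs], method = "BH")
  rapid <- out$p_adj_h1_h0 < alpha &
    (is.na(out$p_h2_h1) | out$p_h2_h1 >= alpha) &
    out$omega_fg > out$omega_bg
  positive <- !is.na(out$p_adj_bs) & out$p_adj_bs < alpha
  out$decision <- dplyr::case_when(
    rapid & positive ~ "both",
    rapid ~ "rapidly_evolving",
    positive ~ "positively_selected",
    TRUE ~ "none"
  )
  class(out) <- c("lrt_tbl", class(tibble()))
  out
}

#' @export
tidy.codon_fit <- function(x, ...) {
  tibble(term = c(names(x$omega), "kappa", "scale"),
         estimate = c(unname(x$omega), x$kappa, x$scale))
}

#' @export
glance.codon_fit <- function(x, ...) {
  tibble(hypothesis = x$hypothesis, logLik = x$loglik, npar = x$npar,
         converged = x$convergence)
}
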
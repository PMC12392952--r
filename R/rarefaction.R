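#' Pan- and core-genome rarefaction curves
#'
#' For random orderings of the genomes, computes `pan(n)` (orthogroups
#' present in at least one of the first `n` genomes) and `core(n)`
#' (orthogroups present in all of the first `n`). Within every ordering
#' `pan` is nondecreasing and `core` nonincreasing. When the number of
#' requested permutations reaches the number of distinct orderings (only
#' feasible for small genome collections, up to 7), all orderings are
#' enumerated exactly once instead of sampled.
#'
#' @param occupancy A `pan_occupancy`.
#' @param n_permutations Number of genome orderings (>= 1).
#' @param seed Integer seed for the ordering draws.
#' @return A tibble of class `pan_rarefaction` with columns `n`, `pan_mean`,
#'   `pan_min`, `pan_max`, `core_mean`, `core_min`, `core_max`; attribute
#'   `curves` holds the per-ordering long table (`perm`, `n`, `pan`,
#'   `core`).
#' @export
rarefaction_curves <- function(occupancy, n_permutations = 100L, seed = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  P <- occupancy_matrix(occupancy) > 0L
  N <- ncol(P)
  exhaustive <- N <= 7L && n_permutations >= factorial(N)
  orderings <- if (exhaustive) {
    permutations_lex(N)
  } else {
    with_seed(seed, lapply(seq_len(n_permutations), function(i) sample.int(N)))
  }
  curves <- map(seq_along(orderings), function(i) {
    ord <- orderings[[i]]
    pan_seen <- rep(FALSE, nrow(P))
    core_seen <- rep(TRUE, nrow(P))
    pan <- integer(N); core <- integer(N)
    for (n in seq_len(N)) {
      col <- P[, ord[n]]
      pan_seen <- pan_seen | col
      core_seen <- core_seen & col
      pan[n] <- sum(pan_seen)
      core[n] <- sum(core_seen)
    }
    tibble(perm = i, n = seq_len(N), pan = pan, core = core)
  }) |> list_rbind()
  out <- curves |>
    group_by(n) |>
    summarise(pan_mean = mean(.data$pan), pan_min = min(.data$pan),
              pan_max = max(.data$pan),
              core_mean = mean(.data$core), core_min = min(.data$core),
              core_max = max(.data$core), .groups = "drop")
  attr(out, "curves") <- curves
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("pan_rarefaction", class(tibble()))
  out
}

#' Fit pangenome openness models to rarefaction curves
#'
#' Fits three descriptive models to the mean curves: the Heaps-law pan-size
#' model `P(n) = kappa * n^gamma` (least squares on the log-log scale); the
#' new-orthogroup discovery decay `deltaP(n) ~ n^(-alpha)`, whose exponent
#' decides openness (`alpha > 1` indicates a closed/restricted pangenome);
#' and an exponential core decay `core(n) = c_inf + a * exp(-n / tau)`,
#' whose asymptote estimates the core size at infinite sampling. A constant
#' pan curve yields `gamma = 0` and `alpha = Inf` (closed).
#'
#' @param curves A `pan_rarefaction` (or any data frame with columns `n`,
#'   `pan_mean`, `core_mean` for `n = 1..N`, `N >= 5`).
#' @return An object of class `openness_fit` with fields `kappa`, `gamma`,
#'   `alpha`, `closed_flag`, `core_asymptote`, `n_points`. [tidy()] and
#'   [glance()] methods are provided.
#' @export
fit_openness <- function(curves) {
  n <- curves$n
  pan <- curves$pan_mean
  core <- curves$core_mean
  if (length(unique(n)) < 4L) stop_validate("openness fit needs >= 4 distinct n values")
  if (any(pan <= 0)) stop_validate("pan curve must be strictly positive")
  heaps <- lm(log(pan) ~ log(n))
  kappa <- exp(unname(coef(heaps)[1L]))
  gamma <- unname(coef(heaps)[2L])
  dn <- n[-1L]
  dp <- diff(pan)
  if (all(dp <= 0)) {
    alpha <- Inf
  } else {
    pos <- dp > 0
    decay <- lm(log(dp[pos]) ~ log(dn[pos]))
    alpha <- -unname(coef(decay)[2L])
  }
  closed <- alpha > 1
  core_asymptote <- tryCatch({
    cinf0 <- min(core)
    a0 <- max(core[1L] - cinf0, 1e-6)
    fit <- suppressWarnings(
      nls(core ~ cinf + a * exp(-n / tau),
          start = list(cinf = cinf0, a = a0, tau = max(n) / 3),
          control = list(warnOnly = TRUE, maxiter = 200L)))
    max(0, unname(coef(fit)["cinf"]))
  }, error = function(e) core[length(core)])
  structure(list(kappa = kappa, gamma = gamma, alpha = alpha,
                 closed_flag = closed, core_asymptote = core_asymptote,
                 n_points = length(n)),
            class = "openness_fit")
}

#' @export
print.openness_fit <- function(x, ...) {
  cat(sprintf("<openness_fit> P(n) = %.4g * n^%.4g; discovery decay alpha = %.4g (%s); core asymptote %.4g\n",
              x$kappa, x$gamma, x$alpha,
              if (x$closed_flag) "closed/restricted" else "open", x$core_asymptote))
  invisible(x)
}

#' @export
tidy.openness_fit <- function(x, ...) {
  tibble(term = c("kappa", "gamma", "alpha", "core_asymptote"),
         estimate = c(x$kappa, x$gamma, x$alpha, x$core_asymptote))
}

#' @export
glance.openness_fit <- function(x, ...) {
  tibble(gamma = x$gamma, alpha = x$alpha, closed = x$closed_flag,
         core_asymptote = x$core_asymptote, n_points = x$n_points)
}
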
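# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "panortho_config_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "panortho_parse_error", ...)
}

stop_validate <- function(msg, ...) {
  abort(msg, class = "panortho_validation_error", ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = "panortho_lookup_error", ...)
}

check_fraction <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop_config(sprintf("`%s` must be a fraction in %s0, 1%s, got %s",
                        name, if (open_lower) "(" else "[",
                        if (open_upper) ")" else "]",
                        format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_config(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

# Deterministic permutation enumeration (lexicographic), small n only.
permutations_lex <- function(n) {
  if (n == 0L) return(list(integer()))
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (sub in permutations_lex(n - 1L)) {
      out[[k]] <- c(first, rest[sub])
      k <- k + 1L
    }
  }
  out
}
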
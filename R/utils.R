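# Internal helpers: argument checks, reproducible seeding, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper || (!allow_zero && x == 0))
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g]",
                  name, x, lower, upper))
  invisible(x)
}

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stage seed from a root seed and a character label.
#'
#' All randomness in multi-stage runs flows from one root seed; each stage
#' uses `derive_seed(seed, "<stage>")` so partial reruns are reproducible.
#' Plain 32-bit-safe integer arithmetic (values stay below 2^31).
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return a single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  check_number(seed, "seed")
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

# Stable content hash (FNV-1a over serialized text) for provenance stamps.
stable_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Pearson r via pairwise-complete observations; returns NA when degenerate.
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# Two-sided p for a Pearson r via the t transform, df = n - 2.
cor_p_value <- function(r, n) {
  if (!is.finite(r) || n < 3L) return(NA_real_)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

# Fisher z with |r| capped below 1 (see greedy objective docs).
fisher_z <- function(r, cap = 0.99) {
  r <- pmax(pmin(r, cap), -cap)
  atanh(r)
}
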
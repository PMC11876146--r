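# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside package
#' functions never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically fold extra integers into a master seed, keeping the
# result a valid 32-bit seed. Linear-congruential mixing in exact double
# arithmetic (all intermediates < 2^53).
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Row-broadcast addition of a bias vector to a matrix.
add_bias <- function(m, b) {
  m + rep(b, rep.int(nrow(m), length(b)))
}
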
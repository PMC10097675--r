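# Internal helpers: hierarchical seed derivation and scoped RNG use.

# Derive a reproducible child seed from a parent seed and a sequence of
# string/integer keys. One global seed drives the whole pipeline; every
# sub-computation (dataset, split, job, fit) mixes its own keys in, so any
# stage can be re-run in isolation. Values stay in [1, 2^31 - 1].
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (key in keys) {
    ints <- if (is.character(key)) {
      unlist(lapply(key, utf8ToInt), use.names = FALSE)
    } else {
      as.double(key)
    }
    for (v in ints) {
      h <- (h * 48271 + abs(v) + 1) %% 2147483647
    }
  }
  as.integer(h + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Binary-matrix validation shared by the kernel and the generators.
check_binary_matrix <- function(X, name = "X") {
  if (!is.matrix(X)) stop(sprintf("'%s' must be a matrix", name))
  if (any(is.na(X)) || !all(X == 0 | X == 1)) {
    stop(sprintf("'%s' must contain only 0/1 entries", name))
  }
  invisible(X)
}

round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
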
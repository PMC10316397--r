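# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Minimum-image convention for displacements on a periodic axis of length L.
min_image <- function(dz, L) {
  dz - L * round(dz / L)
}

# Wrap coordinates into [-L/2, L/2).
wrap_coord <- function(z, L) {
  z - L * floor(z / L + 0.5)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Derive a stream of distinct child seeds from one integer seed, staying
# below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629 + 1
}
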
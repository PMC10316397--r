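# Independent oracles and fixture builders used across the suite.

# Brute-force permeation-event counter: replicates the gate at every
# periodic image in unwrapped coordinates and tracks each image's slab
# with explicit per-step bookkeeping. Written independently of the
# package's region/transition state machine.
oracle_count_events <- function(z, lo, hi, L) {
  if (length(z) < 2) return(list(up = 0L, down = 0L))
  ks <- if (is.finite(L)) {
    seq(floor((min(z) - hi) / L) - 1L, ceiling((max(z) - lo) / L) + 1L)
  } else {
    0L
  }
  up <- 0L; down <- 0L
  for (k in ks) {
    a <- lo + k * ifelse(is.finite(L), L, 0)
    b <- hi + k * ifelse(is.finite(L), L, 0)
    entered_from <- NA_character_
    for (i in 2:length(z)) {
      p <- z[i - 1]; q <- z[i]
      p_in <- p >= a & p <= b
      q_in <- q >= a & q <= b
      if (!p_in && q_in) {
        entered_from <- if (p < a) "below" else "above"
      } else if (p_in && !q_in) {
        if (q > b && identical(entered_from, "below")) up <- up + 1L
        if (q < a && identical(entered_from, "above")) down <- down + 1L
        entered_from <- NA_character_
      } else if (!p_in && !q_in) {
        if (p < a && q > b) up <- up + 1L
        if (p > b && q < a) down <- down + 1L
        entered_from <- NA_character_
      }
    }
  }
  list(up = up, down = down, net = up - down)
}

# Seeded biased random walk in unwrapped coordinates.
make_random_walk <- function(n, drift, sd, z0 = 0) {
  z0 + cumsum(c(0, rnorm(n - 1, mean = drift, sd = sd)))
}

# Wrap an unwrapped series into [-L/2, L/2).
wrap_series <- function(z, L) z - L * floor(z / L + 0.5)

# Minimal trajectory tibble around per-ion z series (x = y = 0).
toy_trajectory <- function(z_by_ion, times = NULL, L = 80, species = "ion") {
  ions <- seq_along(z_by_ion)
  nfr <- length(z_by_ion[[1]])
  times <- times %||% (seq_len(nfr) - 1)
  df <- dplyr::bind_rows(lapply(ions, function(i) {
    tibble::tibble(frame = seq_len(nfr), time = times, particle_id = i,
                   species = species, x = 0, y = 0, z = z_by_ion[[i]])
  }))
  structure(df, box = c(30, 30, L),
            class = c("pore_trajectory", class(tibble::tibble())))
}

`%||%` <- rlang::`%||%`
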
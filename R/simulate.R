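# Brownian-dynamics generator: overdamped Langevin ions in a cylindrical
# pore under an axial PMF plus a constant-field voltage term; waters are
# resampled per stored frame from the occupancy implied by the dewetting
# factor (the downstream analyses need occupancy statistics, not water
# kinetics).

# Axial PMF (kcal/mol) from Gaussian components, periodic over L.
pmf_potential <- function(z, pmf_terms, L) {
  u <- numeric(length(z))
  if (nrow(pmf_terms) == 0) return(u)
  for (j in seq_len(nrow(pmf_terms))) {
    h <- pmf_terms$height[j]; c0 <- pmf_terms$center[j]; w <- pmf_terms$width[j]
    for (k in -1:1) {
      d <- z - c0 - k * L
      u <- u + h * exp(-d^2 / (2 * w^2))
    }
  }
  u
}

# Axial force -dU/dz (kcal/mol/A), periodic over L.
pmf_force <- function(z, pmf_terms, L) {
  f <- numeric(length(z))
  if (nrow(pmf_terms) == 0) return(f)
  for (j in seq_len(nrow(pmf_terms))) {
    h <- pmf_terms$height[j]; c0 <- pmf_terms$center[j]; w <- pmf_terms$width[j]
    for (k in -1:1) {
      d <- z - c0 - k * L
      f <- f + h * d / w^2 * exp(-d^2 / (2 * w^2))
    }
  }
  f
}

# Sample z from exp(-U/kT) on a fine grid by inverse transform.
sample_boltzmann_z <- function(n, pmf_terms, L, kT) {
  zg <- seq(-L / 2, L / 2, length.out = 2001L)
  w <- exp(-pmf_potential(zg, pmf_terms, L) / kT)
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  # strip duplicated CDF values (flat zero-weight stretches)
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], zg[keep], xout = runif(n), rule = 2)$y
}

# Sample water positions: uniform over the cylinder except the gate slab,
# where the density is scaled by (1 - dewetting_factor).
sample_waters <- function(n, spec) {
  L <- spec$box_lengths[3]
  lo <- spec$gate_region[1]; hi <- spec$gate_region[2]
  f <- spec$dewetting_factor
  Lg <- hi - lo
  seg1 <- lo + L / 2                 # weight-1 length below the gate
  seg2 <- (1 - f) * Lg               # effective gate length
  W <- (L - Lg) + seg2
  u <- runif(n, 0, W)
  z <- ifelse(
    u < seg1, -L / 2 + u,
    ifelse(u < seg1 + seg2, lo + (u - seg1) / (1 - f), hi + (u - seg1 - seg2))
  )
  # f == 1: seg2 = 0, so no draw lands in the gate branch
  r <- spec$pore_radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Simulate ions and waters in a cylindrical pore
#'
#' Integrates overdamped Langevin dynamics for the ions of a [pore_spec()]:
#' \deqn{\Delta z = \frac{D}{k_B T} F(z)\,\Delta t + \sqrt{2 D \Delta t}\,\eta,}
#' with \eqn{F(z) = -dU_{\rm PMF}/dz + q e V / L_z} and \eqn{\eta} a standard
#' normal deviate. Ions also diffuse laterally and are confined to the pore
#' cylinder by rejection (a step landing outside the radius is resampled by
#' keeping the previous lateral position). The axial coordinate is periodic
#' over Lz. Initial ion z is drawn from the Boltzmann distribution of the
#' PMF so that equilibrium statistics are available from the first frame.
#' Waters are resampled independently at every stored frame.
#'
#' The run is deterministic for a given `seed`: the same spec and seed give
#' bitwise-identical trajectories.
#'
#' @param spec A [pore_spec()].
#' @param replicate_id Integer tag recorded in the trajectory metadata.
#' @param seed Seed for this run; defaults to `spec$seed`.
#' @return A `pore_trajectory`: a tibble with columns `frame`, `time` (ps),
#'   `particle_id`, `species` (`"ion"` or `"water"`), `x`, `y`, `z`
#'   (Angstrom), and attributes `spec`, `box`, `replicate_id`, `seed`,
#'   `fingerprint`.
#' @export
#' @examples
#' spec <- pore_spec(n_ions = 2, n_waters = 20, n_steps = 200,
#'                   frame_stride = 20, seed = 7)
#' traj <- simulate_pore(spec)
#' dplyr::count(traj, species)
simulate_pore <- function(spec, replicate_id = 1L, seed = spec$seed) {
  validate_pore_spec(spec)
  L <- spec$box_lengths[3]
  kT <- KB_KCAL * spec$temperature
  D <- spec$diffusion_coeff
  dt <- spec$dt
  mu <- D / kT
  f_volt <- spec$ion_charge * spec$voltage * EV_KCAL / L

  # force lookup table on a fine grid
  dz_grid <- 0.05
  zg <- seq(-L / 2, L / 2, by = dz_grid)
  fg <- pmf_force(zg, spec$pmf_terms, L) + f_volt
  if (any(!is.finite(fg))) {
    rlang::abort("Non-finite PMF force on the grid; check PMF widths.")
  }
  max_drift <- max(abs(mu * fg * dt))
  if (max_drift > L / 10) {
    rlang::abort(sprintf(
      "Time step too large: max drift step %.3g A exceeds Lz/10 = %.3g A.",
      max_drift, L / 10))
  }

  n_ions <- spec$n_ions
  n_steps <- spec$n_steps
  stride <- spec$frame_stride
  n_stored <- n_steps %/% stride
  sigma <- sqrt(2 * D * dt)
  R2 <- spec$pore_radius^2

  with_seed(seed, {
    z <- sample_boltzmann_z(n_ions, spec$pmf_terms, L, kT)
    r0 <- spec$pore_radius * sqrt(runif(n_ions))
    th0 <- runif(n_ions, 0, 2 * pi)
    x <- r0 * cos(th0); y <- r0 * sin(th0)

    ion_x <- matrix(0, n_stored + 1L, n_ions)
    ion_y <- matrix(0, n_stored + 1L, n_ions)
    ion_z <- matrix(0, n_stored + 1L, n_ions)
    ion_x[1L, ] <- x; ion_y[1L, ] <- y; ion_z[1L, ] <- z

    half <- L / 2
    inv_dz <- 1 / dz_grid
    row <- 2L
    for (s in seq_len(n_steps)) {
      eta <- rnorm(3L * n_ions)
      idx <- as.integer(round((z + half) * inv_dz)) + 1L
      z <- z + mu * fg[idx] * dt + sigma * eta[seq_len(n_ions)]
      z <- z - L * floor(z / L + 0.5)
      xp <- x + sigma * eta[(n_ions + 1L):(2L * n_ions)]
      yp <- y + sigma * eta[(2L * n_ions + 1L):(3L * n_ions)]
      ok <- (xp * xp + yp * yp) <= R2
      x <- ifelse(ok, xp, x)
      y <- ifelse(ok, yp, y)
      if (s %% stride == 0L) {
        ion_x[row, ] <- x; ion_y[row, ] <- y; ion_z[row, ] <- z
        row <- row + 1L
      }
    }

    n_frames <- n_stored + 1L
    n_wat <- spec$n_waters
    wat <- sample_waters(n_frames * n_wat, spec)

    frame_ids <- seq_len(n_frames)
    times <- c(0, seq_len(n_stored) * stride) * dt

    ion_part <- tibble::tibble(
      frame = rep(frame_ids, each = n_ions),
      time = rep(times, each = n_ions),
      particle_id = rep(seq_len(n_ions), times = n_frames),
      species = "ion",
      x = as.vector(t(ion_x)),
      y = as.vector(t(ion_y)),
      z = as.vector(t(ion_z))
    )
    out <- ion_part
    if (n_wat > 0L) {
      wat_part <- tibble::tibble(
        frame = rep(frame_ids, each = n_wat),
        time = rep(times, each = n_wat),
        particle_id = rep(n_ions + seq_len(n_wat), times = n_frames),
        species = "water",
        x = wat[, "x"], y = wat[, "y"], z = wat[, "z"]
      )
      out <- dplyr::bind_rows(ion_part, wat_part) |>
        dplyr::arrange(.data$frame, .data$particle_id)
    }
    new_pore_trajectory(out, spec = spec, replicate_id = replicate_id,
                        seed = seed)
  })
}

new_pore_trajectory <- function(df, spec, replicate_id, seed) {
  structure(
    df,
    spec = spec,
    box = spec$box_lengths,
    replicate_id = as.integer(replicate_id),
    seed = as.integer(seed),
    fingerprint = spec_fingerprint(spec),
    class = c("pore_trajectory", class(tibble::tibble()))
  )
}

#' Simulate a set of replicate trajectories
#'
#' Runs [simulate_pore()] `n_replicates` times with distinct seeds derived
#' from `base_seed`, mirroring the replicate protocol of channel MD studies
#' (six replicas by default).
#'
#' @param spec A [pore_spec()].
#' @param n_replicates Number of replicas.
#' @param base_seed Integer; per-replicate seeds are derived from it.
#' @return A list of `pore_trajectory` objects, one per replicate.
#' @export
simulate_replicates <- function(spec, n_replicates = 6L, base_seed = spec$seed) {
  seeds <- derive_seeds(base_seed, n_replicates)
  purrr::map(seq_len(n_replicates), function(i) {
    simulate_pore(spec, replicate_id = i, seed = seeds[i])
  })
}

#' Box dimensions of a trajectory
#' @param traj A `pore_trajectory`.
#' @return Numeric length-3 box lengths in Angstrom.
#' @export
trajectory_box <- function(traj) {
  box <- attr(traj, "box", exact = TRUE)
  if (is.null(box)) rlang::abort("`traj` has no box attribute.")
  box
}

#' @export
print.pore_trajectory <- function(x, ...) {
  nf <- length(unique(x$frame))
  np <- length(unique(x$particle_id))
  cat(sprintf("<pore_trajectory> %d frames x %d particles (replicate %s, seed %s)\n",
              nf, np,
              attr(x, "replicate_id") %||% NA, attr(x, "seed") %||% NA))
  NextMethod()
}
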
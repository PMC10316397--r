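# Well-tempered metadynamics on the axial ion coordinate of the toy pore,
# free-energy reconstruction from the hill history, and a
# Boltzmann-inversion oracle for validation.

#' Well-tempered metadynamics parameters
#'
#' @param w0 Initial hill height in kcal/mol.
#' @param sigma Hill width in Angstrom.
#' @param stride Deposition stride in integration steps.
#' @param gamma Bias factor (> 1); heights are tempered by
#'   `exp(-V_bias / ((gamma - 1) kT))`, so large `gamma` approaches
#'   standard metadynamics.
#' @param kT Thermal energy in kcal/mol (0.596 at 300 K).
#' @return A `metad_params` list.
#' @export
metad_params <- function(w0 = 0.3, sigma = 1.0, stride = 500L, gamma = 10,
                         kT = 0.596) {
  stopifnot_scalar_number(w0, "w0", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  stopifnot_scalar_number(kT, "kT", positive = TRUE)
  if (!is.finite(gamma) || gamma <= 1) rlang::abort("`gamma` must be > 1.")
  if (stride < 1) rlang::abort("`stride` must be >= 1.")
  structure(list(w0 = w0, sigma = sigma, stride = as.integer(stride),
                 gamma = gamma, kT = kT),
            class = "metad_params")
}

# Gaussian and its derivative summed over periodic images k in -1:1.
periodic_gauss <- function(z, center, sigma, L) {
  g <- 0
  for (k in -1:1) {
    d <- z - center - if (is.finite(L)) k * L else 0
    g <- g + exp(-d^2 / (2 * sigma^2))
    if (!is.finite(L)) break
  }
  g
}

#' Run well-tempered metadynamics on the ion axial coordinate
#'
#' Propagates a single tagged ion (the collective-variable carrier) with
#' the same overdamped Langevin scheme as [simulate_pore()], adding the
#' metadynamics bias force. Every `params$stride` steps a Gaussian hill is
#' deposited at the current CV value with tempered height
#' \eqn{w = w_0 \exp(-V_{\rm bias}(s) / ((\gamma - 1) k T))}. The CV is
#' periodic over the box, handled by minimum-image Gaussian images. The
#' applied voltage is zeroed for the run: the permeation free energy is an
#' equilibrium property, computed separately from conduction runs.
#'
#' @param spec A [pore_spec()]; its PMF is the landscape being
#'   reconstructed.
#' @param params A [metad_params()].
#' @param seed Seed; defaults to `spec$seed`.
#' @param cv_stride Store the CV trajectory every this many steps.
#' @return A list of class `wtmetad_result` with elements `hills` (tibble
#'   `step`, `center`, `height`, `width`), `cv` (tibble `time`, `z`),
#'   `params`, `spec`.
#' @export
run_wt_metadynamics <- function(spec, params = metad_params(),
                                seed = spec$seed, cv_stride = 10L) {
  validate_pore_spec(spec)
  if (!inherits(params, "metad_params")) rlang::abort("`params` must be metad_params().")
  L <- spec$box_lengths[3]
  kT <- KB_KCAL * spec$temperature
  D <- spec$diffusion_coeff
  dt <- spec$dt
  mu <- D / kT

  dz_grid <- 0.1
  zg <- seq(-L / 2, L / 2, by = dz_grid)
  ng <- length(zg)
  f_pmf <- pmf_force(zg, spec$pmf_terms, L)
  if (any(!is.finite(f_pmf))) {
    rlang::abort("Non-finite PMF force on the grid; check PMF widths.")
  }
  v_bias <- numeric(ng)
  f_bias <- numeric(ng)

  n_steps <- spec$n_steps
  stride <- params$stride
  sigma_hill <- params$sigma
  w0 <- params$w0
  gamma <- params$gamma
  kT_hill <- params$kT
  sig_step <- sqrt(2 * D * dt)
  half <- L / 2
  inv_dz <- 1 / dz_grid

  n_hills_max <- n_steps %/% stride
  hill_center <- double(n_hills_max)
  hill_height <- double(n_hills_max)
  hill_step <- integer(n_hills_max)
  nh <- 0L

  n_cv <- n_steps %/% cv_stride
  cv_z <- double(n_cv)
  icv <- 0L

  with_seed(seed, {
    z <- sample_boltzmann_z(1L, spec$pmf_terms, L, kT)
    noise <- rnorm(n_steps)
    for (s in seq_len(n_steps)) {
      idx <- as.integer(round((z + half) * inv_dz)) + 1L
      if (idx < 1L) idx <- 1L else if (idx > ng) idx <- ng
      z <- z + mu * (f_pmf[idx] + f_bias[idx]) * dt + sig_step * noise[s]
      z <- z - L * floor(z / L + 0.5)
      if (s %% stride == 0L) {
        idx <- as.integer(round((z + half) * inv_dz)) + 1L
        if (idx < 1L) idx <- 1L else if (idx > ng) idx <- ng
        w <- w0 * exp(-v_bias[idx] / ((gamma - 1) * kT_hill))
        if (!is.finite(w) || w <= 0) {
          rlang::abort("Non-finite or non-positive tempered hill height.")
        }
        nh <- nh + 1L
        hill_center[nh] <- z
        hill_height[nh] <- w
        hill_step[nh] <- s
        # update bias potential and force tables with the new hill
        for (k in -1:1) {
          d <- zg - z - k * L
          g <- w * exp(-d^2 / (2 * sigma_hill^2))
          v_bias <- v_bias + g
          f_bias <- f_bias + g * d / sigma_hill^2
        }
        if (any(!is.finite(v_bias))) rlang::abort("Non-finite bias potential.")
      }
      if (s %% cv_stride == 0L) {
        icv <- icv + 1L
        cv_z[icv] <- z
      }
    }
  })

  hills <- tibble::tibble(step = hill_step[seq_len(nh)],
                          center = hill_center[seq_len(nh)],
                          height = hill_height[seq_len(nh)],
                          width = sigma_hill)
  cv <- tibble::tibble(time = seq_len(n_cv) * cv_stride * dt, z = cv_z)
  structure(list(hills = hills, cv = cv, params = params, spec = spec,
                 seed = as.integer(seed)),
            class = "wtmetad_result")
}

#' Reconstruct the free-energy profile from metadynamics hills
#'
#' Evaluates the accumulated bias \eqn{V_{\rm bias}(z)} (with periodic
#' Gaussian images when `period` is finite) and applies the well-tempered
#' estimator \eqn{F(z) = -\frac{\gamma}{\gamma - 1} V_{\rm bias}(z)},
#' shifted so that min(F) = 0.
#'
#' @param hills Hill tibble (`center`, `height`, `width`), e.g. from
#'   [run_wt_metadynamics()].
#' @param z_grid Grid on which to evaluate F.
#' @param gamma Bias factor used in the run.
#' @param period Periodic length of the CV, or `Inf` for a non-periodic CV.
#' @param tail_average Fraction of the deposition history (from the end)
#'   over which the bias potential is time-averaged before applying the
#'   estimator; 0 uses the final bias only. Averaging over the converged
#'   tail damps the hill-by-hill fluctuation of the estimate.
#' @return A `free_energy_profile` tibble (`z`, `F` in kcal/mol), with the
#'   minimum shifted to zero.
#' @export
#' @examples
#' h <- tibble::tibble(center = 0, height = 1, width = 2)
#' fe <- reconstruct_free_energy(h, seq(-30, 30, 0.5), gamma = 10)
#' max(fe$F) # 10/9: a single unit hill is scaled by gamma/(gamma-1)
reconstruct_free_energy <- function(hills, z_grid, gamma, period = Inf,
                                    tail_average = 0) {
  if (is.null(hills) || nrow(hills) == 0L) rlang::abort("empty hill list.")
  if (!is.finite(gamma) || gamma <= 1) rlang::abort("`gamma` must be > 1.")
  n <- nrow(hills)
  n0 <- max(1L, n - as.integer(floor(tail_average * n)) + 0L)
  # time average of the prefix-sum bias over checkpoints n0..n reduces to
  # per-hill weights (n - max(j, n0) + 1) / (n - n0 + 1)
  wts <- (n - pmax(seq_len(n), n0) + 1) / (n - n0 + 1)
  v <- numeric(length(z_grid))
  for (j in seq_len(n)) {
    v <- v + wts[j] * hills$height[j] *
      periodic_gauss(z_grid, hills$center[j], hills$width[j], period)
  }
  f <- -gamma / (gamma - 1) * v
  new_free_energy_profile(z_grid, f - min(f))
}

new_free_energy_profile <- function(z, f) {
  structure(tibble::tibble(z = z, F = f),
            class = c("free_energy_profile", class(tibble::tibble())))
}

#' Boltzmann-inversion free energy from an unbiased trajectory
#'
#' Histogram estimator \eqn{F(z) = -kT \ln \rho(z) + C} on the grid bins,
#' min-shifted; empty bins are masked as NA. Used as the independent
#' cross-check of the metadynamics estimator. The input must be unbiased
#' and voltage-free.
#'
#' @param traj A `pore_trajectory` from a voltage-free run.
#' @param z_grid Bin-center grid (uniform spacing).
#' @param kT Thermal energy in kcal/mol.
#' @return A `free_energy_profile` with NA at unvisited bins.
#' @export
boltzmann_invert <- function(traj, z_grid, kT = 0.596) {
  spec <- attr(traj, "spec", exact = TRUE)
  if (!is.null(spec) && spec$voltage != 0) {
    rlang::abort("Boltzmann inversion needs a voltage-free trajectory.")
  }
  z <- traj$z[traj$species == "ion"]
  if (length(z) < 1e4) {
    rlang::warn(sprintf(
      "Only %d ion samples; Boltzmann-inversion estimate will be noisy.",
      length(z)))
  }
  dz <- diff(z_grid[1:2])
  edges <- c(z_grid - dz / 2, tail(z_grid, 1) + dz / 2)
  # findInterval returns 0 below range and n+1 above; tabulate drops both
  counts <- tabulate(findInterval(z, edges, rightmost.closed = TRUE),
                     nbins = length(z_grid))
  f <- ifelse(counts > 0, -kT * log(counts), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_free_energy_profile(z_grid, f)
}

#' Permeation barrier from a free-energy profile
#'
#' \eqn{\Delta F^\ddagger} = max F over the gate region minus min F over
#' the reference region, invariant under additive shifts of F.
#'
#' @param profile A `free_energy_profile`.
#' @param gate_region Length-2 z-range of the gate (barrier) region.
#' @param reference_region Length-2 z-range of the bulk-like reference.
#' @return Barrier height in kcal/mol.
#' @export
barrier_height <- function(profile, gate_region, reference_region) {
  gsel <- profile$z >= gate_region[1] & profile$z <= gate_region[2]
  rsel <- profile$z >= reference_region[1] & profile$z <= reference_region[2]
  fg <- profile$F[gsel]; fr <- profile$F[rsel]
  if (!any(gsel) || all(is.na(fg))) rlang::abort("gate region empty on the grid.")
  if (!any(rsel) || all(is.na(fr))) rlang::abort("reference region empty on the grid.")
  max(fg, na.rm = TRUE) - min(fr, na.rm = TRUE)
}

#' Write or read a PLUMED-style hills table
#'
#' Four-column TSV: `step`, `center`, `height`, `width`.
#'
#' @param hills Hill tibble.
#' @param path File path.
#' @return `write_hills()`: `path` invisibly; `read_hills()`: the hill
#'   tibble.
#' @export
write_hills <- function(hills, path) {
  utils::write.table(hills[, c("step", "center", "height", "width")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write a free-energy profile as TSV (`z`, `F`)
#' @param profile A `free_energy_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_free_energy <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
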
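#' Specify a cylindrical pore system for Brownian-dynamics simulation
#'
#' A `pore_spec` collects everything needed to generate a synthetic
#' trajectory of cations and waters in a cylindrical channel pore: the box,
#' the pore geometry, the axial potential of mean force (PMF), the applied
#' transmembrane voltage, particle counts and the integrator settings.
#' Units follow molecular-dynamics conventions: Angstrom, picosecond,
#' kcal/mol, Kelvin, elementary charges.
#'
#' The PMF is a sum of Gaussian components
#' \eqn{U(z) = \sum_j h_j \exp(-(z-c_j)^2 / (2 w_j^2))} evaluated with
#' periodic images over the box length. The voltage enters as a uniform
#' axial force \eqn{q e V / L_z} on ions only (constant-field convention).
#' Waters are resampled every stored frame from the occupancy implied by
#' `dewetting_factor`: uniform outside the gate region, scaled by
#' `1 - dewetting_factor` inside it, so 0 means a bulk-like gate and 1 a
#' fully dewetted gate.
#'
#' @param box_lengths Numeric length-3, box edge lengths (Lx, Ly, Lz) in
#'   Angstrom. The pore axis is z and z is periodic over Lz.
#' @param pore_radius Cylinder radius in Angstrom.
#' @param gate_region Numeric length-2 `(z_low, z_high)` in Angstrom, the
#'   activation-gate slab used for dewetting and event counting.
#' @param pmf_terms Data frame with columns `height` (kcal/mol, may be
#'   negative for wells), `center` (Angstrom) and `width` (Angstrom, > 0).
#'   Use `NULL` or a zero-row frame for a flat PMF.
#' @param voltage Transmembrane voltage in volts across Lz (signed;
#'   positive drives a positive ion toward +z).
#' @param n_ions Number of cations.
#' @param ion_charge Ion charge in elementary charges.
#' @param diffusion_coeff Ion diffusion coefficient in Angstrom^2/ps.
#' @param temperature Temperature in Kelvin.
#' @param n_waters Number of water particles resampled per stored frame.
#' @param dewetting_factor Dimensionless in `[0, 1]`.
#' @param dt Integration time step in ps.
#' @param n_steps Number of integration steps.
#' @param frame_stride Store every `frame_stride`-th step. If it does not
#'   divide `n_steps` the trailing remainder steps are simulated but not
#'   stored (truncation).
#' @param seed Integer seed controlling all randomness of the run.
#'
#' @return An object of class `pore_spec` (a validated named list).
#' @seealso [simulate_pore()]
#' @export
#' @examples
#' spec <- pore_spec(n_steps = 1000, n_waters = 50, seed = 1)
#' spec$gate_region
pore_spec <- function(box_lengths = c(30, 30, 80),
                      pore_radius = 5,
                      gate_region = c(-10, 10),
                      pmf_terms = NULL,
                      voltage = 0,
                      n_ions = 6,
                      ion_charge = 1,
                      diffusion_coeff = 0.02,
                      temperature = 300,
                      n_waters = 210,
                      dewetting_factor = 0,
                      dt = 1,
                      n_steps = 1e5,
                      frame_stride = 50,
                      seed = 1L) {
  if (is.null(pmf_terms)) {
    pmf_terms <- tibble::tibble(height = double(), center = double(), width = double())
  }
  pmf_terms <- tibble::as_tibble(pmf_terms)
  spec <- structure(
    list(
      box_lengths = as.double(box_lengths),
      pore_radius = as.double(pore_radius),
      gate_region = as.double(gate_region),
      pmf_terms = pmf_terms,
      voltage = as.double(voltage),
      n_ions = as.integer(n_ions),
      ion_charge = as.double(ion_charge),
      diffusion_coeff = as.double(diffusion_coeff),
      temperature = as.double(temperature),
      n_waters = as.integer(n_waters),
      dewetting_factor = as.double(dewetting_factor),
      dt = as.double(dt),
      n_steps = as.integer(n_steps),
      frame_stride = as.integer(frame_stride),
      seed = as.integer(seed)
    ),
    class = "pore_spec"
  )
  validate_pore_spec(spec)
}

#' Validate a pore specification
#'
#' Checks the invariants of a [pore_spec()]: gate inside the box, positive
#' widths and diffusion coefficient, `dewetting_factor` in `[0, 1]`,
#' positive time step.
#'
#' @param spec A `pore_spec`.
#' @return `spec`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_pore_spec <- function(spec) {
  if (!inherits(spec, "pore_spec")) rlang::abort("`spec` must be a `pore_spec`.")
  bl <- spec$box_lengths
  if (length(bl) != 3L || any(!is.finite(bl)) || any(bl <= 0)) {
    rlang::abort("`box_lengths` must be three positive finite numbers.")
  }
  stopifnot_scalar_number(spec$pore_radius, "pore_radius", positive = TRUE)
  g <- spec$gate_region
  if (length(g) != 2L || any(!is.finite(g)) || g[1] >= g[2]) {
    rlang::abort("`gate_region` must satisfy z_low < z_high.")
  }
  if (g[1] < -bl[3] / 2 || g[2] > bl[3] / 2) {
    rlang::abort("`gate_region` must lie inside the box (-Lz/2, Lz/2).")
  }
  pt <- spec$pmf_terms
  if (!all(c("height", "center", "width") %in% names(pt))) {
    rlang::abort("`pmf_terms` needs columns height, center, width.")
  }
  if (nrow(pt) > 0 && any(!is.finite(pt$width) | pt$width <= 0)) {
    rlang::abort("All PMF widths must be > 0.")
  }
  stopifnot_scalar_number(spec$diffusion_coeff, "diffusion_coeff", positive = TRUE)
  stopifnot_scalar_number(spec$temperature, "temperature", positive = TRUE)
  stopifnot_scalar_number(spec$dt, "dt", positive = TRUE)
  if (spec$dewetting_factor < 0 || spec$dewetting_factor > 1) {
    rlang::abort("`dewetting_factor` must be in [0, 1].")
  }
  if (spec$n_ions < 1L) rlang::abort("`n_ions` must be >= 1.")
  if (spec$n_waters < 0L) rlang::abort("`n_waters` must be >= 0.")
  if (spec$n_steps < 1L) rlang::abort("`n_steps` must be >= 1.")
  if (spec$frame_stride < 1L) rlang::abort("`frame_stride` must be >= 1.")
  invisible(spec)
}

#' @export
print.pore_spec <- function(x, ...) {
  cat("<pore_spec>\n")
  cat(sprintf("  box: %g x %g x %g A, pore radius %g A\n",
              x$box_lengths[1], x$box_lengths[2], x$box_lengths[3], x$pore_radius))
  cat(sprintf("  gate: [%g, %g] A, dewetting %g\n",
              x$gate_region[1], x$gate_region[2], x$dewetting_factor))
  cat(sprintf("  PMF terms: %d; voltage %g V; %d ions (q = %+g e), %d waters\n",
              nrow(x$pmf_terms), x$voltage, x$n_ions, x$ion_charge, x$n_waters))
  cat(sprintf("  D = %g A^2/ps, T = %g K, dt = %g ps, %d steps (stride %d), seed %d\n",
              x$diffusion_coeff, x$temperature, x$dt, x$n_steps,
              x$frame_stride, x$seed))
  invisible(x)
}

# Short fingerprint of a spec for trajectory metadata.
spec_fingerprint <- function(spec) {
  key <- paste(
    paste(spec$box_lengths, collapse = ","), spec$pore_radius,
    paste(spec$gate_region, collapse = ","),
    paste(unlist(spec$pmf_terms), collapse = ","),
    spec$voltage, spec$n_ions, spec$ion_charge, spec$diffusion_coeff,
    spec$temperature, spec$n_waters, spec$dewetting_factor,
    spec$dt, spec$n_steps, spec$frame_stride,
    sep = "|"
  )
  # Tiny rolling-polynomial hash; only used as an identity tag.
  bytes <- as.integer(charToRaw(key))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("spec-%010d", h)
}
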
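# Time-averaged axial water-density profiles in a cylindrical sampling
# volume, bulk normalization and hydrated/dehydrated calls for the
# activation gate.

#' Axial water-density profile of a pore
#'
#' Bins water positions inside a cylinder of radius `cylinder_radius` about
#' the pore (z) axis into axial slabs and averages over all frames:
#' per-bin density = mean in-bin water count / (pi r^2 dz), in waters per
#' cubic Angstrom. If `bulk` is supplied (waters/A^3) the profile also
#' carries `normalized = density / bulk`.
#'
#' @param traj A `pore_trajectory` (or tibble with `frame`, `species`,
#'   `x`, `y`, `z`).
#' @param cylinder_radius Sampling cylinder radius in Angstrom.
#' @param bin_width Axial bin width in Angstrom.
#' @param z_range Length-2 axial range; defaults to the box.
#' @param bulk Optional bulk density for normalization; see
#'   [bulk_density()].
#' @return A `density_profile` tibble: `z_mid`, `density`, `normalized`
#'   (NA when no bulk is given), with attributes `bin_edges`,
#'   `bulk_density`, `cylinder_radius`, `n_frames_averaged`.
#' @export
water_density_profile <- function(traj, cylinder_radius = 5, bin_width = 1,
                                  z_range = NULL, bulk = NULL) {
  stopifnot_scalar_number(cylinder_radius, "cylinder_radius", positive = TRUE)
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  n_frames <- length(unique(traj$frame))
  if (n_frames == 0L) rlang::abort("trajectory has zero frames.")
  if (is.null(z_range)) {
    L <- trajectory_box(traj)[3]
    z_range <- c(-L / 2, L / 2)
  }
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (tail(edges, 1) < z_range[2]) edges <- c(edges, z_range[2])
  wat <- traj[traj$species == "water" &
                (traj$x^2 + traj$y^2) <= cylinder_radius^2 &
                traj$z >= z_range[1] & traj$z <= z_range[2], , drop = FALSE]
  counts <- if (nrow(wat) > 0) {
    tabulate(findInterval(wat$z, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1L)
  } else {
    rep(0L, length(edges) - 1L)
  }
  vol <- pi * cylinder_radius^2 * diff(edges)
  dens <- counts / n_frames / vol
  bulkd <- if (is.null(bulk)) NA_real_ else as.double(bulk)
  out <- tibble::tibble(
    z_mid = (head(edges, -1) + tail(edges, -1)) / 2,
    density = dens,
    normalized = if (is.na(bulkd)) NA_real_ else dens / bulkd
  )
  structure(out,
            bin_edges = edges,
            bulk_density = bulkd,
            cylinder_radius = cylinder_radius,
            n_frames_averaged = n_frames,
            class = c("density_profile", class(tibble::tibble())))
}

#' Bulk water density from a reference slab
#'
#' Mean water density (waters/A^3) in a cylindrical slab far from the
#' gate, used to normalize pore hydration profiles.
#'
#' @inheritParams water_density_profile
#' @param reference_slab Length-2 z-range of the reference slab; it should
#'   lie outside the gate region.
#' @return Bulk density in waters per cubic Angstrom.
#' @export
bulk_density <- function(traj, reference_slab, cylinder_radius = 5) {
  if (length(reference_slab) != 2L || reference_slab[1] >= reference_slab[2]) {
    rlang::abort("`reference_slab` must be (z_low, z_high) with z_low < z_high.")
  }
  n_frames <- length(unique(traj$frame))
  if (n_frames == 0L) rlang::abort("trajectory has zero frames.")
  wat <- traj[traj$species == "water" &
                (traj$x^2 + traj$y^2) <= cylinder_radius^2 &
                traj$z >= reference_slab[1] & traj$z < reference_slab[2], ,
              drop = FALSE]
  vol <- pi * cylinder_radius^2 * diff(reference_slab)
  if (vol <= 0) rlang::abort("reference slab has zero volume.")
  if (nrow(wat) == 0L) rlang::abort("reference slab contains no waters.")
  nrow(wat) / n_frames / vol
}

#' Classify gate hydration from a density profile
#'
#' Takes the minimum normalized water density over the gate bins and calls
#' the gate `dehydrated` (min < `dehydrated_below`), `partially_dehydrated`
#' (min < `partial_below`) or `hydrated`. The default cutoffs 0.05 and 0.5
#' are package choices: channel MD studies report hydration qualitatively
#' ("continuously hydrated" vs "complete dehydration around the activation
#' gate") rather than with numeric thresholds.
#'
#' @param profile A `density_profile` with a finite `normalized` column.
#' @param gate A [gate_definition()] (or length-2 numeric range).
#' @param dehydrated_below,partial_below Classification cutoffs on the
#'   minimum normalized density.
#' @return A `hydration_call` tibble with `min_normalized_density` and
#'   `class`.
#' @export
classify_gate_hydration <- function(profile, gate,
                                    dehydrated_below = 0.05,
                                    partial_below = 0.5) {
  rng <- if (inherits(gate, "gate_definition")) c(gate$z_low, gate$z_high) else gate
  sel <- profile$z_mid >= rng[1] & profile$z_mid <= rng[2]
  if (!any(sel)) rlang::abort("gate lies outside the profile range.")
  mn <- profile$normalized[sel]
  if (all(is.na(mn))) rlang::abort("profile has no normalized densities; supply `bulk`.")
  m <- min(mn, na.rm = TRUE)
  cls <- if (m < dehydrated_below) "dehydrated"
         else if (m < partial_below) "partially_dehydrated"
         else "hydrated"
  structure(tibble::tibble(min_normalized_density = m, class = cls),
            class = c("hydration_call", class(tibble::tibble())))
}
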
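# Permeation-event detection and single-channel conductance estimation.
# Events are complete traversals of the activation-gate slab; conductance
# follows the event-counting definition g = |N| q e / (T |V|).

#' Define the activation-gate slab
#'
#' @param z_low,z_high Gate boundaries in Angstrom (`z_low < z_high`). The
#'   pore axis is z and the extracellular side is +z.
#' @return A `gate_definition` list.
#' @export
gate_definition <- function(z_low = -10, z_high = 10) {
  if (!is.finite(z_low) || !is.finite(z_high) || z_low >= z_high) {
    rlang::abort("gate must satisfy z_low < z_high.")
  }
  structure(list(z_low = z_low, z_high = z_high, axis = "z(+extracellular)"),
            class = "gate_definition")
}

#' Unwrap ion axial coordinates across the periodic boundary
#'
#' Converts wrapped per-frame z positions into continuous series using the
#' minimum-image convention on consecutive displacements. Input that is
#' already continuous is returned unchanged (a displacement smaller than
#' half the box is never altered by the minimum image).
#'
#' @param traj A `pore_trajectory` (or tibble with `frame`, `time`,
#'   `particle_id`, `species`, `z`).
#' @param box_length Periodic box length Lz; defaults to the trajectory box.
#' @param species Which species to unwrap (default ions).
#' @return A tibble `ion_id`, `time`, `z` with continuous `z`, ordered by
#'   ion then time.
#' @export
#' @examples
#' tr <- tibble::tibble(frame = 1:2, time = c(0, 1), particle_id = 1,
#'                      species = "ion", z = c(39, -39))
#' unwrap_axial(tr, box_length = 80)$z # 39, 41
unwrap_axial <- function(traj, box_length = NULL, species = "ion") {
  L <- box_length %||% trajectory_box(traj)[3]
  ions <- traj[traj$species %in% species, c("particle_id", "time", "z")]
  ions <- ions[order(ions$particle_id, ions$time), ]
  out <- ions |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_modify(function(d, key) {
      dz <- diff(d$z)
      dm <- min_image(dz, L)
      big <- which(abs(dm) >= L / 2 * (1 - 1e-9))
      if (length(big) > 0) {
        rlang::warn(sprintf(
          "ion %s: displacement >= Lz/2 between frames %d and %d; unwrap ambiguous.",
          format(key$particle_id), big[1], big[1] + 1L))
      }
      d$z <- d$z[1] + c(0, cumsum(dm))
      d
    }) |>
    dplyr::ungroup()
  tibble::tibble(ion_id = out$particle_id, time = out$time, z = out$z)
}

#' Detect ion permeation events through the gate
#'
#' Runs a double-gate state machine on each ion's continuous axial series:
#' an event of direction +1 is recorded when an ion that last entered the
#' gate slab from below `z_low` first exits above `z_high` (mirror image
#' for -1). Re-crossings inside the slab do not double-count; each
#' completed traversal counts exactly once. The gate is periodic with the
#' box, so an ion drifting through several box images records one event
#' per traversal.
#'
#' @param z_series Tibble from [unwrap_axial()] (`ion_id`, `time`, `z` with
#'   continuous z), or a plain numeric vector for a single ion.
#' @param gate A [gate_definition()].
#' @param box_length Periodic box length Lz used to place gate images; use
#'   `Inf` for non-periodic series.
#' @param replicate_id Optional tag attached to the events.
#' @return A tibble of events: `ion_id`, `time` (completion time),
#'   `direction` (+1 toward +z, -1 toward -z), `replicate_id`. Zero rows if
#'   no event.
#' @export
detect_permeation_events <- function(z_series, gate, box_length = Inf,
                                     replicate_id = NA_integer_) {
  if (is.numeric(z_series) && is.null(dim(z_series))) {
    z_series <- tibble::tibble(ion_id = 1L, time = seq_along(z_series) - 1,
                               z = as.double(z_series))
  }
  if (nrow(z_series) == 0L) {
    return(tibble::tibble(ion_id = integer(), time = double(),
                          direction = integer(), replicate_id = integer()))
  }
  L <- box_length
  lo <- gate$z_low; hi <- gate$z_high
  if (is.finite(L) && (hi - lo) >= L) rlang::abort("gate wider than the box.")
  res <- z_series |>
    dplyr::group_by(.data$ion_id) |>
    dplyr::group_modify(function(d, key) {
      detect_events_one(d$z, d$time, lo, hi, L)
    }) |>
    dplyr::ungroup()
  res$replicate_id <- as.integer(replicate_id)
  res
}

# State machine for one ion. Regions of the wrapped coordinate relative to
# the gate: B (below), G (inside), A (above). Transitions across the
# periodic boundary (B<->A with the "wrong" displacement sign) are not gate
# crossings.
detect_events_one <- function(z, tm, lo, hi, L) {
  region <- function(zz) {
    zw <- if (is.finite(L)) wrap_coord(zz - (lo + hi) / 2, L) + (lo + hi) / 2 else zz
    ifelse(zw < lo, 1L, ifelse(zw <= hi, 2L, 3L)) # 1=B, 2=G, 3=A
  }
  r <- region(z)
  armed <- 0L # 0 none, +1 entered from below, -1 entered from above
  times <- double(); dirs <- integer()
  for (i in seq_along(r)[-1]) {
    r1 <- r[i - 1L]; r2 <- r[i]
    if (r2 == r1) next
    du <- z[i] - z[i - 1L]
    if (r1 == 1L && r2 == 2L) armed <- 1L
    else if (r1 == 3L && r2 == 2L) armed <- -1L
    else if (r1 == 2L && r2 == 3L) {
      if (armed == 1L) { times <- c(times, tm[i]); dirs <- c(dirs, 1L) }
      armed <- 0L
    } else if (r1 == 2L && r2 == 1L) {
      if (armed == -1L) { times <- c(times, tm[i]); dirs <- c(dirs, -1L) }
      armed <- 0L
    } else if (r1 == 1L && r2 == 3L) {
      # up through the whole gate, or down across the periodic boundary
      if (du > 0) { times <- c(times, tm[i]); dirs <- c(dirs, 1L) }
      armed <- 0L
    } else if (r1 == 3L && r2 == 1L) {
      if (du < 0) { times <- c(times, tm[i]); dirs <- c(dirs, -1L) }
      armed <- 0L
    }
  }
  tibble::tibble(time = times, direction = dirs)
}

#' Convert permeation events to a conductance estimate
#'
#' Uses the event-counting definition
#' \deqn{g = |N_{\rm net}| \, q \, e / (T \, |V|),}
#' with \eqn{N_{\rm net}} the signed count of events in the field direction
#' minus events against it, \eqn{e} the elementary charge
#' (1.602176634e-19 C), \eqn{T} the observation time and \eqn{V} the
#' applied voltage. Reported in picosiemens. With the printed convention of
#' single-channel MD studies, 5 events in 100 ns at 0.5 V and q = 1 give
#' 16.02 pS.
#'
#' @param events Event tibble from [detect_permeation_events()], or a
#'   single signed net event count.
#' @param duration_ps Observation time T in ps.
#' @param voltage Applied voltage in volts (non-zero).
#' @param charge Ion charge q in elementary charges.
#' @return A `conductance_estimate` object; see also
#'   [replicate_conductance()] for replicate statistics.
#' @export
#' @examples
#' estimate_conductance(5, duration_ps = 1e5, voltage = -0.5)$conductance_pS
estimate_conductance <- function(events, duration_ps, voltage, charge = 1) {
  stopifnot_scalar_number(duration_ps, "duration_ps", positive = TRUE)
  stopifnot_scalar_number(voltage, "voltage")
  if (voltage == 0) {
    rlang::abort("voltage is 0: conductance is undefined from drift counting.")
  }
  field_dir <- sign(charge * voltage)
  n_net <- if (is.numeric(events) && is.null(dim(events))) {
    as.double(events)
  } else {
    sum(events$direction) * field_dir
  }
  g <- abs(n_net) * abs(charge) * E_COULOMB / (duration_ps * 1e-12 * abs(voltage))
  structure(
    list(
      n_events_net = n_net,
      duration_ps = duration_ps,
      voltage = voltage,
      charge_per_ion = charge,
      conductance_pS = g * 1e12,
      per_replicate_pS = NULL,
      mean_pS = g * 1e12,
      sem_pS = NA_real_
    ),
    class = "conductance_estimate"
  )
}

#' Replicate-resolved conductance with standard error
#'
#' Converts per-replicate signed net event counts to per-replicate
#' conductances, their mean and the standard error of the mean (sample SD
#' over sqrt(n), n - 1 denominator), matching the replicate-error
#' convention of MD conductance estimates.
#'
#' @param per_replicate_counts Signed net event counts (field direction
#'   positive), one per replicate; length >= 2.
#' @inheritParams estimate_conductance
#' @return A `conductance_estimate` with `per_replicate_pS`, `mean_pS` and
#'   `sem_pS` filled in.
#' @export
#' @examples
#' replicate_conductance(rep(2, 6), duration_ps = 1e5, voltage = -0.5)$mean_pS
replicate_conductance <- function(per_replicate_counts, duration_ps, voltage,
                                  charge = 1) {
  if (length(per_replicate_counts) < 2L) {
    rlang::abort("need >= 2 replicates: SEM undefined otherwise.")
  }
  stopifnot_scalar_number(duration_ps, "duration_ps", positive = TRUE)
  if (voltage == 0) {
    rlang::abort("voltage is 0: conductance is undefined from drift counting.")
  }
  per_g <- per_replicate_counts * abs(charge) * E_COULOMB /
    (duration_ps * 1e-12 * abs(voltage)) * 1e12
  structure(
    list(
      n_events_net = sum(per_replicate_counts),
      duration_ps = duration_ps,
      voltage = voltage,
      charge_per_ion = charge,
      conductance_pS = mean(per_g),
      per_replicate_pS = per_g,
      mean_pS = mean(per_g),
      sem_pS = stats::sd(per_g) / sqrt(length(per_g))
    ),
    class = "conductance_estimate"
  )
}

#' Net signed event counts per replicate
#'
#' Convenience wrapper: unwraps, detects events and returns the signed net
#' count (field direction positive) for one trajectory.
#'
#' @param traj A `pore_trajectory`.
#' @param gate A [gate_definition()].
#' @return Integer signed net event count in the field direction.
#' @export
count_net_events <- function(traj, gate) {
  spec <- attr(traj, "spec", exact = TRUE)
  L <- trajectory_box(traj)[3]
  zs <- unwrap_axial(traj, box_length = L)
  ev <- detect_permeation_events(zs, gate, box_length = L,
                                 replicate_id = attr(traj, "replicate_id"))
  fd <- if (!is.null(spec)) sign(spec$ion_charge * spec$voltage) else 1
  if (fd == 0) fd <- 1
  as.integer(sum(ev$direction) * fd)
}

#' Compare conductance samples of two pore models
#'
#' Two-sided Welch (unequal-variance) t-test on per-replicate conductance
#' samples, the usual significance screen for "is model A's conductance
#' different from model B's". Degenerate zero-variance inputs are handled
#' by convention: identical constant samples give p = 1, distinct constant
#' samples give p = 0.
#'
#' @param g_samples_a,g_samples_b Numeric vectors (length >= 2 each) of
#'   per-replicate conductances in pS.
#' @return A tibble with `statistic`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(g_samples_a, g_samples_b) {
  if (length(g_samples_a) < 2L || length(g_samples_b) < 2L) {
    rlang::abort("each sample must have >= 2 values.")
  }
  va <- stats::var(g_samples_a); vb <- stats::var(g_samples_b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(g_samples_a), mean(g_samples_b)))
    return(tibble::tibble(statistic = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0,
                          mean_a = mean(g_samples_a), mean_b = mean(g_samples_b)))
  }
  tt <- stats::t.test(g_samples_a, g_samples_b, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 mean_a = mean(g_samples_a), mean_b = mean(g_samples_b))
}
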
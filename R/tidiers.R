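# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a conductance estimate
#'
#' @param x A `conductance_estimate`.
#' @param ... Unused.
#' @return One row per replicate (`replicate`, `g_pS`), or a single row
#'   for an unreplicated estimate.
#' @method tidy conductance_estimate
#' @export
tidy.conductance_estimate <- function(x, ...) {
  if (is.null(x$per_replicate_pS)) {
    tibble::tibble(replicate = 1L, g_pS = x$conductance_pS)
  } else {
    tibble::tibble(replicate = seq_along(x$per_replicate_pS),
                   g_pS = x$per_replicate_pS)
  }
}

#' @rdname tidy.conductance_estimate
#' @return `glance()`: a one-row tibble with `mean_g_pS`, `sem_g_pS`,
#'   `n_replicates`, `n_events_net`, `duration_ps`, `voltage`.
#' @method glance conductance_estimate
#' @export
glance.conductance_estimate <- function(x, ...) {
  tibble::tibble(
    mean_g_pS = x$mean_pS,
    sem_g_pS = x$sem_pS,
    n_replicates = length(x$per_replicate_pS %||% 1L),
    n_events_net = x$n_events_net,
    duration_ps = x$duration_ps,
    voltage = x$voltage
  )
}

#' Tidy a free-energy profile
#' @param x A `free_energy_profile`.
#' @param ... Unused.
#' @return A plain tibble `z`, `F`.
#' @method tidy free_energy_profile
#' @export
tidy.free_energy_profile <- function(x, ...) {
  tibble::tibble(z = x$z, F = x$F)
}

#' Tidy a metadynamics result
#' @param x A `wtmetad_result`.
#' @param ... Unused.
#' @return The hill table (`step`, `center`, `height`, `width`).
#' @method tidy wtmetad_result
#' @export
tidy.wtmetad_result <- function(x, ...) {
  x$hills
}

#' @rdname tidy.wtmetad_result
#' @return `glance()`: one row with `n_hills`, `final_height`, `gamma`.
#' @method glance wtmetad_result
#' @export
glance.wtmetad_result <- function(x, ...) {
  tibble::tibble(n_hills = nrow(x$hills),
                 final_height = tail(x$hills$height, 1),
                 gamma = x$params$gamma)
}

#' Tidy a pipeline run report
#' @param x A `run_report`.
#' @param ... Unused.
#' @return The scenario table.
#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) {
  tibble::as_tibble(x$scenarios)
}

#' @rdname tidy.run_report
#' @return `glance()`: one row with scenario and class counts.
#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  s <- x$scenarios
  tibble::tibble(
    n_scenarios = nrow(s),
    n_ok = sum(s$status == "ok"),
    n_fully_conductive = sum(s$class == "fully_conductive", na.rm = TRUE),
    n_subconductance = sum(s$class == "subconductance", na.rm = TRUE),
    n_nonconducting = sum(s$class == "nonconducting", na.rm = TRUE)
  )
}
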
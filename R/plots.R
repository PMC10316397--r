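# ggplot2 visualisations of the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_errorbar
#'   geom_hline geom_rect labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot an axial water-density profile
#'
#' Normalized density against z with the gate region shaded; the bulk
#' level (1) is drawn as a dashed line.
#'
#' @param object A `density_profile`.
#' @param gate Optional [gate_definition()] to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, gate = NULL, ...) {
  d <- tibble::as_tibble(object)
  ycol <- if (all(is.na(d$normalized))) "density" else "normalized"
  p <- ggplot(d, aes(x = .data$z_mid, y = .data[[ycol]])) +
    geom_line(linewidth = 0.7, colour = "#2166ac") +
    labs(x = "z (Å)",
         y = if (ycol == "normalized") "water density / bulk" else
           "water density (Å⁻³)") +
    theme_minimal()
  if (ycol == "normalized") {
    p <- p + geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40")
  }
  if (!is.null(gate)) {
    p <- p + ggplot2::annotate("rect", xmin = gate$z_low, xmax = gate$z_high,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "#b2182b")
  }
  p
}

#' Plot a free-energy profile
#'
#' @param object A `free_energy_profile`.
#' @param gate Optional [gate_definition()] to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot free_energy_profile
#' @export
autoplot.free_energy_profile <- function(object, gate = NULL, ...) {
  p <- ggplot(tibble::as_tibble(object), aes(x = .data$z, y = .data$F)) +
    geom_line(linewidth = 0.7, colour = "#762a83") +
    labs(x = "z (Å)", y = "F (kcal/mol)") +
    theme_minimal()
  if (!is.null(gate)) {
    p <- p + ggplot2::annotate("rect", xmin = gate$z_low, xmax = gate$z_high,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "#b2182b")
  }
  p
}

#' Plot per-scenario conductance with replicate SEM
#'
#' Bar plot of mean conductance per scenario with SEM error bars, colour
#' coded by conductance class — the package's analogue of the
#' conductance-comparison panels of channel MD studies.
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot run_report
#' @export
autoplot.run_report <- function(object, ...) {
  s <- tibble::as_tibble(object$scenarios)
  s <- s[s$status == "ok", ]
  s$scenario <- factor(s$scenario, levels = s$scenario[order(-s$mean_g_pS)])
  ggplot(s, aes(x = .data$scenario, y = .data$mean_g_pS, fill = .data$class)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean_g_pS - .data$sem_g_pS,
                      ymax = .data$mean_g_pS + .data$sem_g_pS),
                  width = 0.25) +
    ggplot2::scale_fill_manual(values = c(
      fully_conductive = "#e08214", subconductance = "#878787",
      nonconducting = "#4393c3")) +
    labs(x = NULL, y = "conductance (pS)", fill = "class") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
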
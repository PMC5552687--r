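# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot
NULL

#' Plot a relaxed reaction path profile
#'
#' @param object A `reaction_path`.
#' @param ... Unused.
#' @return A ggplot: per-bead energy (relative to the first bead) against
#'   cumulative arc length.
#' @export
autoplot.reaction_path <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arc_length,
                                  y = .data$energy_rel)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "arc length (Å)",
                  y = "energy relative to reactant (kcal/mol)",
                  title = "Relaxed reaction path") +
    ggplot2::theme_minimal()
}

#' Plot a multi-level PMF profile
#'
#' @param object An `ml_pmf`.
#' @param ... Unused.
#' @return A ggplot of the ESP, LOW and HIGH profiles per bead with
#'   high-tier error bars.
#' @export
autoplot.ml_pmf <- function(object, ...) {
  p <- object$profile
  d <- tidyr::pivot_longer(
    p[, c("bead", "dW_esp", "dW_low", "dW_high")],
    -"bead", names_to = "level", values_to = "dW")
  d$level <- factor(d$level, levels = c("dW_esp", "dW_low", "dW_high"),
                    labels = c("ESP", "LOW", "HIGH"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bead, y = .data$dW,
                                  colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      data = tibble::tibble(bead = p$bead, dW = p$dW_high,
                            level = factor("HIGH",
                                           c("ESP", "LOW", "HIGH")),
                            lo = p$dW_high - p$se_high,
                            hi = p$dW_high + p$se_high),
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    ggplot2::labs(x = "bead", y = expression(Delta * W ~ "(kcal/mol)"),
                  colour = "tier",
                  title = "Multi-level potential of mean force") +
    ggplot2::theme_minimal()
}

#' Plot a solvent decomposition
#'
#' @param object A `solvent_decomposition`.
#' @param ... Unused.
#' @return A ggplot of the gas-phase, internal (gas + polarization) and
#'   aqueous profiles per bead.
#' @export
autoplot.solvent_decomposition <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("bead", "gas", "internal", "aqueous")],
    -"bead", names_to = "component", values_to = "energy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bead, y = .data$energy,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bead", y = "energy (kcal/mol)",
                  title = "Solvent / polarization decomposition") +
    ggplot2::theme_minimal()
}
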
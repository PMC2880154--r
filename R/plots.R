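#' Plot a pairwise-invasion grid
#'
#' Tile map of the sign of invasion fitness over (resident, mutant) trait
#' pairs; "+" regions (mutant invades) in dark, "-" in light, the neutral
#' diagonal in grey. Vertical sign flips locate singular strategies.
#'
#' @param object A [pip_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pip_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(resident, mutant,
                                       fill = factor(sign_lambda))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`-1` = "grey90", `0` = "grey60", `1` = "grey25"),
      labels = c(`-1` = "mutant dies out", `0` = "neutral",
                 `1` = "mutant invades"),
      name = NULL, na.value = "white") +
    ggplot2::labs(
      x = sprintf("resident trait (%s locus)", attr(object, "locus")),
      y = "mutant trait") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot an ESS sweep
#'
#' One swept axis: ESS phenotype curves per sex against the axis. Two axes:
#' heat maps of the female and male ESS traits over the grid.
#'
#' @param object An [ess_sweep()] tibble.
#' @param trait Column to display on two-axis sweeps (default the male
#'   recovery rate `"gamma_m"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ess_sweep <- function(object, trait = "gamma_m", ...) {
  axes <- attr(object, "axes")
  df <- tibble::as_tibble(object)
  if (length(axes) == 1) {
    long <- tidyr::pivot_longer(
      df, dplyr::all_of(c("x_f_star", "x_m_star")),
      names_to = "trait", values_to = "value")
    ggplot2::ggplot(long,
                    ggplot2::aes(.data[[axes[1]]], value, colour = trait)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_colour_manual(
        values = c(x_f_star = "#b2182b", x_m_star = "#2166ac"),
        labels = c(x_f_star = "female ESS", x_m_star = "male ESS"),
        name = NULL) +
      ggplot2::labs(x = axes[1], y = "ESS trait value") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                     fill = .data[[trait]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = trait) +
      ggplot2::labs(x = axes[1], y = axes[2]) +
      ggplot2::theme_minimal()
  }
}

#' Plot the phenotype maps of a trade-off model
#'
#' Curves of recovery rate, background mortality and fecundity during
#' infection against the underlying trait, on a grid inside (0, 1).
#'
#' @param model A [tradeoff_model()].
#' @param params A [host_params()].
#' @param n Grid resolution.
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(model, params = host_params(), n = 101) {
  grid <- seq(0.01, 0.99, length.out = n)
  long <- tidyr::pivot_longer(phenotype_at(grid, model, params),
                              c("gamma", "d", "phi"),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x, value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "defence trait x", y = NULL,
                  title = sprintf("trade-off model (%s)", model$kind)) +
    ggplot2::theme_minimal()
}
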
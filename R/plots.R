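# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_hline facet_wrap labs scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

#' Plot a landscape raster
#'
#' @param object A [build_landscape()] object.
#' @param ... Unused.
#' @return A ggplot: optimal patches on the matrix background.
#' @export
autoplot.vole_landscape <- function(object, ...) {
  cells <- as_tibble(object)
  ggplot(cells, aes(.data$x, .data$y, fill = .data$habitat)) +
    geom_raster() +
    scale_fill_manual(values = c(optimal = "#33a02c", matrix = "grey92")) +
    labs(
      x = "x (cells)", y = "y (cells)",
      title = sprintf(
        "%d patch(es), %.2f%% optimal habitat",
        object$n_patches, 100 * object$habitat_fraction
      )
    ) +
    theme_minimal()
}

#' Plot simulated vole density trajectories
#'
#' @param object A [run_scenario()] result.
#' @param log10_scale Show log10 density (the conventional display for
#'   vole series).
#' @param ... Unused.
#' @return A ggplot of annual density per replicate.
#' @export
autoplot.vole_sim <- function(object, log10_scale = TRUE, ...) {
  d <- object$census
  p <- ggplot(d, aes(.data$year, .data$density_optimal_ha)) +
    geom_line(colour = "#1f78b4") +
    facet_wrap(~replicate, labeller = "label_both") +
    labs(
      x = "year", y = "voles / ha optimal habitat",
      title = sprintf(
        "%s predators, %d patch(es), %s season",
        object$config$predator_assembly, object$config$n_patches,
        object$config$season$length
      )
    ) +
    theme_minimal()
  if (log10_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an ANOVA variance decomposition
#'
#' @param object An [anova_decompose()] table.
#' @param ... Unused.
#' @return A ggplot bar chart of the adjusted R-squared contribution per
#'   source.
#' @export
autoplot.vc_anova <- function(object, ...) {
  d <- object[object$source != "Residual", ]
  d$source <- factor(d$source, levels = d$source)
  ggplot(d, aes(.data$source, .data$adj_r2_pct)) +
    geom_col(fill = "#1f78b4") +
    labs(
      x = NULL, y = "% variation accounted for (adj.)",
      title = attr(object, "response")
    ) +
    theme_minimal()
}

#' Plot an autocorrelation function with its confidence band
#'
#' @param x Numeric series (typically log densities).
#' @param alpha Band significance level.
#' @param max_lag Largest lag (default as in [acf_values()]).
#' @return A ggplot of ACF values by lag with the white-noise band.
#' @export
plot_acf <- function(x, alpha = 0.05, max_lag = NULL) {
  r <- acf_values(x, max_lag)
  ci <- ci_halfwidth(length(x), alpha)
  d <- tibble(lag = seq_along(r) - 1L, acf = r)
  ggplot(d, aes(.data$lag, .data$acf)) +
    ggplot2::geom_segment(aes(xend = .data$lag, yend = 0)) +
    geom_hline(yintercept = c(-ci, ci), linetype = 2, colour = "#1f78b4") +
    geom_hline(yintercept = 0) +
    labs(x = "lag (years)", y = "ACF") +
    theme_minimal()
}
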
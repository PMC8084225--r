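#' Plot a fitted z-curve
#'
#' The standard 2D presentation: per-replicate z points along phylogenetic
#' distance, the penalized-spline fit with its gray 95% band, and brown
#' reference lines at the 95% limits around zero z (values between them
#' are non-significant).
#'
#' @param object An `eaa_smooth` curve fit.
#' @param show_points Draw the underlying z points (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eaa_smooth <- function(object, show_points = TRUE, ...) {
  if (object$kind == "surface") {
    return(plot_surface(object))
  }
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96),
                        color = "brown", linewidth = 0.4) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), linewidth = 0.8) +
    ggplot2::labs(x = "Phylogenetic distance (Ma to LCA)", y = "z-value") +
    ggplot2::theme_minimal()
  if (show_points && !is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data, ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.25, size = 0.7
    )
  }
  p
}

#' Plot a fitted z-surface
#'
#' Raster view of the tensor-product smooth over physical and phylogenetic
#' distance: regions whose fitted z lies inside the null band are gray,
#' significant regions are heat-colored by z.
#'
#' @param fit An `eaa_smooth` surface fit.
#' @return A ggplot.
#' @export
plot_surface <- function(fit) {
  stopifnot(inherits(fit, "eaa_smooth"), fit$kind == "surface")
  g <- fit$grid
  g$z_shown <- ifelse(g$significant, g$fit, NA_real_)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$physical, y = .data$phylo)) +
    ggplot2::geom_raster(fill = "grey80") +
    ggplot2::geom_raster(data = g[g$significant, ],
                         ggplot2::aes(fill = .data$fit)) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "green3", high = "blue",
                                  midpoint = 0, name = "z") +
    ggplot2::labs(x = "Physical distance (m, annulus mean radius)",
                  y = "Phylogenetic distance (Ma)") +
    ggplot2::theme_minimal()
}

#' Quick-look plot of an EAA result
#'
#' Per-replicate z points of one test against phylogenetic distance,
#' faceted by annulus, colored by focal group.
#'
#' @param object An `eaa_result`.
#' @param test Test id to show (default: first present).
#' @param annuli Annuli to facet over (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eaa_result <- function(object, test = NULL, annuli = 1, ...) {
  df <- tibble::as_tibble(object)
  test <- test %||% min(df$test)
  df <- df[df$test == test & df$annulus %in% annuli & !is.na(df$z), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phylo_ma, y = .data$z,
                                   color = .data$group)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96),
                        color = "brown", linewidth = 0.4) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(
      method = "gam",
      formula = y ~ s(x, k = min(8, max(3, length(unique(df$phylo_bin)) - 1))),
      se = TRUE, linewidth = 0.7
    ) +
    ggplot2::facet_wrap(~annulus, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Phylogenetic distance (Ma to LCA)", y = "z-value",
                  title = sprintf("EAA Test %d", test)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
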
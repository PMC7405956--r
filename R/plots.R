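#' @import ggplot2
NULL

#' Bland-Altman plot
#'
#' Scatter of pairwise differences against means with the bias (solid),
#' limits of agreement (dashed), and their confidence bands (shaded).
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  bands <- tibble(
    y = c(object$bias, object$loa_lower, object$loa_upper),
    lo = c(object$bias_ci[1], object$loa_lower_ci[1], object$loa_upper_ci[1]),
    hi = c(object$bias_ci[2], object$loa_lower_ci[2], object$loa_upper_ci[2]),
    kind = c("bias", "loa", "loa")
  )
  ggplot(df, aes(x = .data$mean, y = .data$diff)) +
    geom_rect(data = bands, inherit.aes = FALSE,
              aes(xmin = -Inf, xmax = Inf, ymin = .data$lo, ymax = .data$hi),
              fill = "grey80", alpha = 0.5) +
    geom_hline(data = bands, aes(yintercept = .data$y,
                                 linetype = .data$kind), show.legend = FALSE) +
    scale_linetype_manual(values = c(bias = "solid", loa = "dashed")) +
    geom_point(shape = 1) +
    labs(x = "Mean of measurements", y = "First - second",
         title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                         object$bias, object$loa_lower, object$loa_upper)) +
    theme_minimal()
}

#' Thickness topography plot
#'
#' Layer thickness against signed eccentricity for one or more gridded (or
#' recentred) profiles.
#'
#' @param profile tibble with `ecc_mm` and layer columns.
#' @param layers layer columns to draw.
#' @return a ggplot.
#' @export
plot_thickness_profile <- function(profile, layers = c("GCL", "IPL")) {
  long <- pivot_longer(profile[, c("ecc_mm", intersect(layers, names(profile)))],
                       -"ecc_mm", names_to = "layer", values_to = "thickness_um")
  meta <- attr(profile, "meta") %||% list()
  labs_x <- if (identical(meta$orientation, "vertical")) {
    "Eccentricity (mm): inferior (-) to superior (+)"
  } else {
    "Eccentricity (mm): temporal (-) to nasal (+)"
  }
  ggplot(long, aes(x = .data$ecc_mm, y = .data$thickness_um,
                   colour = .data$layer)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = labs_x, y = "Thickness (µm)", colour = NULL) +
    theme_minimal()
}

#' Quadrant AUC comparison plot
#'
#' Group-wise distribution of a quadrant metric (e.g. `ratio_NT`) per layer.
#'
#' @param metrics per-eye metrics tibble (from a `fovtopo_run`'s
#'   `selected` or `metrics` element) with a `group` column.
#' @param metric column to plot.
#' @param layers layers to include.
#' @return a ggplot.
#' @export
plot_quadrant_metric <- function(metrics, metric = "ratio_NT",
                                 layers = c("GCL", "IPL")) {
  df <- metrics[metrics$layer %in% layers & !is.na(metrics[[metric]]), ]
  ggplot(df, aes(x = .data$group, y = .data[[metric]], colour = .data$group)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6, shape = 1) +
    facet_wrap(~layer, scales = "free_y") +
    labs(x = NULL, y = metric) +
    guides(colour = "none") +
    theme_minimal()
}
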
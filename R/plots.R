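#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_col geom_point
#'   geom_jitter labs scale_color_gradient2 coord_equal theme_minimal
#' @export
ggplot2::autoplot

#' Boxplot of SAI by cohort group
#'
#' @param sai_tab Tibble from [sai_cohort()] (needs `group` and `sai`).
#' @return A ggplot.
#' @export
plot_sai_groups <- function(sai_tab) {
  df <- dplyr::filter(sai_tab, !is.na(.data$sai))
  ggplot(df, aes(x = .data$group, y = .data$sai)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = NULL, y = "SAI (log asymmetry weight)") +
    theme_minimal()
}

#' Bar chart of LASSO selection frequencies
#'
#' @param x A [run_protocol()] result.
#' @param top Number of leading features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lasso_protocol
#' @export
autoplot.lasso_protocol <- function(x, top = 15, ...) {
  df <- head(x$selection_frequency, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$frequency_pct, y = .data$feature)) +
    geom_col() +
    labs(x = "selection frequency (%)", y = NULL) +
    theme_minimal()
}

#' Flat (x, y) rendering of a signature heat map
#'
#' Projects the base-mesh vertices to the frontal plane and colors them by
#' the heat-map scalar (blue-green-red diverging, saturating at the clip).
#'
#' @param x A [heat_map()].
#' @param base The base mesh supplying vertex positions.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heat_map
#' @export
autoplot.heat_map <- function(x, base, ...) {
  df <- tibble(x = base$vertices[, 1], y = base$vertices[, 2],
               scalar = x$scalars)
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$scalar)) +
    geom_point(size = 0.8) +
    scale_color_gradient2(low = "blue", mid = "green", high = "red",
                          limits = c(-x$clip, x$clip), oob = scales_squish) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", color = paste0("z (", x$axis, ")")) +
    theme_minimal()
}

# minimal squish so we avoid a scales dependency in Imports
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Scree plot of DSM mode variance fractions
#'
#' @param x A [fit_dsm()] model.
#' @param n_modes Number of leading modes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dsm_model
#' @export
autoplot.dsm_model <- function(x, n_modes = min(30, length(x$variances)), ...) {
  df <- head(tidy(x), n_modes)
  ggplot(df, aes(x = .data$mode, y = .data$variance_fraction)) +
    geom_col() +
    labs(x = "mode", y = "variance fraction") +
    theme_minimal()
}
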
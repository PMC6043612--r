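#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_raster geom_point
#'   geom_boxplot labs scale_fill_viridis_c theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the fitted vs empirical cumulative onset distribution
#'
#' @param object An `onset_fit` from [onset_distribution_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onset_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curves, c("empirical", "predicted"),
                           names_to = "curve", values_to = "cdf")
  ggplot(d, aes(x = .data$time_h, y = .data$cdf, linetype = .data$curve)) +
    geom_step() +
    labs(x = "time [h]", y = "cumulative onset fraction",
         title = sprintf("onset distribution (sup distance %.3f)",
                         object$sup_distance)) +
    theme_minimal()
}

#' Plot a quasi-potential landscape
#'
#' @param object A `quasi_potential` from [quasi_potential()].
#' @param ... Unused.
#' @return A ggplot (raster of -log occupancy, wells marked).
#' @export
autoplot.quasi_potential <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$A, y = .data$B)) +
    geom_raster(aes(fill = .data$potential)) +
    scale_fill_viridis_c(direction = -1, na.value = "white") +
    geom_point(data = object$wells, colour = "red", shape = 4, size = 3) +
    labs(x = "A (PU.1-like) [molecules]", y = "B (GATA1-like) [molecules]",
         fill = "-log P") +
    theme_minimal()
}

#' Boxplot of production slopes by relative generation
#'
#' @param grouped Output of [group_by_relative_generation()].
#' @return A ggplot.
#' @export
plot_slope_groups <- function(grouped) {
  grouped$relative_generation <-
    factor(grouped$relative_generation, levels = c("-1", "0", "+1", "onset"))
  ggplot(grouped, aes(x = .data$relative_generation, y = .data$slope)) +
    geom_boxplot() +
    labs(x = "generation relative to predicted decision",
         y = "production slope [units/h]") +
    theme_minimal()
}

#' Ternary-free view of the colony-frequency sweep
#'
#' Plots the curve traced by the branching-process model in colony-frequency
#' space as `p_gm` varies (GM vs MegE frequency; the mixed frequency is the
#' complement).
#'
#' @param sweep Output of [sweep_pgm()].
#' @return A ggplot.
#' @export
plot_colony_sweep <- function(sweep) {
  ggplot(sweep, aes(x = .data$F_GM, y = .data$F_MegE,
                    colour = .data$F_GMMegE)) +
    geom_point() +
    labs(x = "frequency of pure GM colonies",
         y = "frequency of pure MegE colonies",
         colour = "GMMegE") +
    theme_minimal()
}
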
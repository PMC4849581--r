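#' Plot a landscape as fitness or phenotype contours
#'
#' Raster-plus-contour view of a landscape over a grid of log input values,
#' showing either the fitness surface (with its optimal ridge) or the raw
#' phenotype.
#'
#' @param landscape A two-input `ridge_landscape`.
#' @param ln_x,ln_y Grid axes.
#' @param what `"fitness"` or `"phenotype"`.
#' @param s,z_opt Selection parameters for the fitness view.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, ln_x = seq(-1, 2, length.out = 151),
                           ln_y = seq(-1, 2, length.out = 151),
                           what = c("fitness", "phenotype"), s = 1,
                           z_opt = 1) {
  what <- match.arg(what)
  grid <- expand.grid(ln_x = ln_x, ln_y = ln_y)
  z <- eval_landscape(landscape, exp(as.matrix(grid)))
  grid$value <- if (what == "fitness") fitness(z, s, z_opt) else z
  ggplot2::ggplot(grid, ggplot2::aes(.data$ln_x, .data$ln_y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value), colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ln x", y = "ln y")
}

#' @export
autoplot.effective_fitness_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ln_x, .data$ln_y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$w_e)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$w_e),
                          breaks = c(0.5, 0.8, 0.99), colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "effective\nfitness") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ln x", y = "ln y")
}

#' @export
autoplot.ridge_sim <- function(object, band = NULL, ...) {
  loc <- corner_localization(object)
  band <- band %||% object$config$sigma_mu
  ggplot2::ggplot(loc$ratios,
                  ggplot2::aes(.data$generation, .data$ratio)) +
    ggplot2::geom_hline(yintercept = exp(band), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "generation", y = "folded input ratio (max/min)",
      subtitle = "dashed: one mutational step from the corner"
    )
}

#' Case epistasis versus relative fitness
#'
#' Scatter of the epistatic fraction against relative fitness across all
#' cases and time points of a [case_control_report()]; the signature of the
#' equilibrium regime is that severely unfit cases are predominantly
#' epistatic.
#'
#' @param report A [case_control_report()] tibble.
#' @param unfit_threshold Reference line for the unfit-case threshold.
#' @return A ggplot object.
#' @export
plot_case_epistasis <- function(report, unfit_threshold = 0.9) {
  ggplot2::ggplot(
    report[!report$degenerate, ],
    ggplot2::aes(.data$relative_fitness, .data$epistatic_fraction)
  ) +
    ggplot2::geom_vline(xintercept = unfit_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "firebrick") +
    ggplot2::labs(x = "case fitness relative to controls",
                  y = "epistatic fraction (H - h)")
}
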
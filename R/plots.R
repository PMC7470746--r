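#' Plot a coculture simulation
#'
#' Consumer-to-releaser ratio over generations on a log axis, with the
#' closed-form predicted steady-state ratio as a dashed reference line.
#'
#' @param object A [simulate_coculture()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coculture_sim
#' @export
autoplot.coculture_sim <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = predict_steady_ratio(params),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Generations", y = "Consumer / releaser ratio (C/R)")
}

#' Plot a standard curve with its calibration points
#'
#' @param object A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concentration (uM)", y = "Response")
}

#' Plot a chromatogram with an optional baseline fit
#'
#' @param chrom A chromatogram data frame (`rt_min`, `signal`).
#' @param baseline Optional [correct_baseline()] result; when supplied the
#'   baseline segment is drawn and the integration bounds are marked.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(chrom, baseline = NULL) {
  p <- ggplot2::ggplot(chrom, ggplot2::aes(x = .data$rt_min,
                                           y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retention time (min)", y = "Signal")
  if (!is.null(baseline)) {
    seg <- baseline$segment
    p <- p +
      ggplot2::geom_segment(
        data = data.frame(x = baseline$left_min_rt, xend = baseline$right_min_rt),
        ggplot2::aes(x = .data$x, xend = .data$xend),
        y = baseline$baseline_slope * baseline$left_min_rt +
          baseline$baseline_intercept,
        yend = baseline$baseline_slope * baseline$right_min_rt +
          baseline$baseline_intercept,
        colour = "firebrick", linetype = "dashed", inherit.aes = FALSE
      ) +
      ggplot2::geom_vline(xintercept = c(baseline$left_min_rt,
                                         baseline$right_min_rt),
                          linetype = "dotted", colour = "grey50")
  }
  p
}

#' Plot relative fitness against starting genotype fraction
#'
#' The standard visual check of frequency-dependent selection: points below
#' the dashed equal-fitness line indicate a disadvantage, and a downward
#' trend indicates negative frequency dependence.
#'
#' @param object A [frequency_dependence()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frequency_dependence
#' @export
autoplot.frequency_dependence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start_fraction,
                                       y = .data$relative_fitness)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Starting fraction of focal genotype",
                  y = "Relative fitness difference")
}
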
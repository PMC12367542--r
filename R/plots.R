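#' Plot a design surface
#'
#' Heat map of the fraction of maximum achievable accuracy over recruited
#' sample size and scan time, with iso-accuracy contours.
#'
#' @param object A `"bwas_surface"`.
#' @param contours Contour levels (default 0.5..0.95).
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot bwas_surface
#' @export
autoplot.bwas_surface <- function(object, contours = c(0.5, 0.6, 0.7, 0.8,
                                                       0.9, 0.95), ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t_min, y = .data$n_recruited,
                                    fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$fraction),
                          breaks = contours, colour = "black",
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Scan time per participant (min)",
                  y = "Recruited sample size",
                  fill = "Fraction of\nmax accuracy")
}

#' Plot observed accuracies against scaling-law fits
#'
#' Observed cell accuracies (points) and the fitted law (lines) against
#' training sample size, one colour per scan time, facetted by phenotype.
#'
#' @param object A `"theor_fit"` tibble.
#' @param data The accuracy table the fits were estimated from.
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot theor_fit
#' @export
autoplot.theor_fit <- function(object, data, ...) {
  if (missing(data)) abort("Supply the accuracy table via `data`.")
  pred <- predict_accuracy(object, data = data)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$n_train,
                                     colour = factor(.data$t_min))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$accuracy), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::facet_wrap(~ .data$dataset + .data$phenotype + .data$metric,
                        scales = "free_y") +
    ggplot2::labs(x = "Training sample size", y = "Prediction accuracy",
                  colour = "Scan time\n(min)")
}

#' Plot a cost-inefficiency curve
#'
#' The scenario-averaged normalized cost inefficiency of fixing scan time
#' at each candidate value; the minimum marks the most cost-effective
#' fixed scan time.
#'
#' @param curve Output of [cost_inefficiency_curve()].
#'
#' @return A ggplot.
#' @export
plot_inefficiency <- function(curve) {
  best <- curve$t_min[which.min(curve$inefficiency)]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t_min,
                                      y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "Fixed scan time per participant (min)",
                  y = "Normalized cost inefficiency")
}

#' Plot cost savings relative to a reference scan time
#'
#' @param savings Output of [savings_vs_reference()].
#'
#' @return A ggplot.
#' @export
plot_savings <- function(savings) {
  ggplot2::ggplot(savings, ggplot2::aes(x = .data$t_min,
                                        y = .data$savings_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Fixed scan time per participant (min)",
                  y = "Cost savings (%)")
}
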
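#' Plot IVIM signal decay curves
#'
#' Normalized bi-exponential signal decay for one or more tissue models and
#' perfusion fractions, on a log signal scale.
#'
#' @param models Tibble of tissue models ([tissue_models()] layout).
#' @param f Perfusion fractions to draw.
#' @param b_grid b-values, s/mm^2.
#' @return A ggplot object.
#' @export
plot_signal_decay <- function(models = tissue_models(),
                              f = c(0.1, 0.2, 0.3),
                              b_grid = seq(0, 1000, by = 25)) {
  dat <- tidyr::expand_grid(model = models$name, f = f) |>
    dplyr::rowwise() |>
    dplyr::reframe(make_signal_set(models[models$name == .data$model, ],
                                   .data$f, b_grid),
                   model = .data$model, f = .data$f)
  ggplot2::ggplot(dat, ggplot2::aes(.data$b, .data$signal,
                                    colour = factor(.data$f))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "b (s/mm²)", y = "S(b)/S(0)", colour = "f")
}

#' Plot per-f error statistics of a Monte-Carlo batch
#'
#' Relative bias (fraction) and coefficient of variation (percent) of the D
#' and f estimates as a function of the true perfusion fraction.
#'
#' @param object An `ivim_errors` tibble from [summarize_errors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ivim_errors
#' @export
autoplot.ivim_errors <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("bias", "cov"), names_to = "statistic") |>
    dplyr::mutate(statistic = dplyr::recode(.data$statistic,
                                            bias = "relative bias",
                                            cov = "CoV (%)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$f_true, .data$value,
                                     colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "true f", y = NULL,
                  title = sprintf("%s %s SNR %g", object$model[1],
                                  object$scheme[1], object$snr[1]))
}

#' Plot the f relative-error surface of a study
#'
#' Tile map of the per-f relative error of the f estimate over scheme x
#' true f, faceted by tissue model and SNR (the contour-style view used to
#' pick optimal schemes).
#'
#' @param object An `ivim_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ivim_study
#' @export
autoplot.ivim_study <- function(object, ...) {
  dat <- object$per_f |>
    dplyr::filter(.data$parameter == "f")
  ggplot2::ggplot(dat, ggplot2::aes(.data$f_true, .data$scheme,
                                    fill = pmin(.data$relerr, 0.5))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(model ~ snr, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "relative error of f\n(capped at 0.5)") +
    ggplot2::labs(x = "true f", y = "b-value scheme")
}

#' Plot a fitted parameter map
#'
#' Raster view of the D and f maps of one slice.
#'
#' @param object An `ivim_map`.
#' @param slice Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ivim_map
#' @export
autoplot.ivim_map <- function(object, slice = NULL, ...) {
  slice <- slice %||% ceiling(dim(object$D_est)[3] / 2)
  dat <- as_tibble(object) |>
    dplyr::filter(.data$slice == !!slice) |>
    tidyr::pivot_longer(c("D_est", "f_est"), names_to = "parameter")
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("scheme %s, slice %d", object$scheme, slice))
}
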
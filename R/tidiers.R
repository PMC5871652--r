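#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a Monte-Carlo batch
#'
#' `tidy()` returns the per-f error statistics (one row per parameter x
#' true f, see [summarize_errors()]); `glance()` the grid-level one-row
#' summary (see [grid_summary()]).
#'
#' @param x An `ivim_mc` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ivim_mc
#' @export
tidy.ivim_mc <- function(x, ...) summarize_errors(x)

#' @rdname tidy.ivim_mc
#' @method glance ivim_mc
#' @export
glance.ivim_mc <- function(x, ...) grid_summary(summarize_errors(x))

#' Tidy a simulation study
#'
#' `tidy()` returns the grid-level error table (one row per model x scheme x
#' SNR); `glance()` a one-row description of the study design.
#'
#' @param x An `ivim_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ivim_study
#' @export
tidy.ivim_study <- function(x, ...) x$grid

#' @rdname tidy.ivim_study
#' @method glance ivim_study
#' @export
glance.ivim_study <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(n_models = nrow(cfg$models), n_schemes = length(cfg$b_low),
                 n_snr = length(cfg$snr), n_f = length(cfg$f_grid),
                 n_iter = cfg$n_iter, calibration = cfg$calibration,
                 seed = cfg$seed %||% NA_integer_)
}

#' Tidy cohort statistics
#'
#' `tidy()` returns the per-subject mean parameters; `glance()` the
#' scheme-level agreement summary (correlation r, Bland-Altman bias, wCV)
#' in one row per parameter.
#'
#' @param x An `ivim_cohort_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ivim_cohort_stats
#' @export
tidy.ivim_cohort_stats <- function(x, ...) x$subject_means

#' @rdname tidy.ivim_cohort_stats
#' @method glance ivim_cohort_stats
#' @export
glance.ivim_cohort_stats <- function(x, ...) {
  out <- dplyr::left_join(
    dplyr::select(x$correlation, "parameter", "r", "p_value"),
    dplyr::select(x$bland_altman, "parameter", ba_bias = "bias",
                  ba_lower = "lower", ba_upper = "upper"),
    by = "parameter")
  if (!is.null(x$repeatability)) {
    wcv <- tidyr::pivot_wider(x$repeatability, names_from = "scheme",
                              values_from = c("wCV", "n_pairs"))
    out <- dplyr::left_join(out, wcv, by = "parameter")
  }
  out
}
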
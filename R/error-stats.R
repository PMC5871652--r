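#' Bias, error and reproducibility statistics
#'
#' Primitive estimator statistics used throughout the simulation study.
#' All use the population (divide-by-N) convention for the standard
#' deviation, and all exclude `NA` estimates (invalid fits):
#'
#' * `relative_bias()`: mean signed deviation normalized by the truth,
#'   `mean(x - X) / X`.
#' * `relative_error()`: root-mean-square distance to the truth normalized
#'   by it, `sqrt(mean((x - X)^2)) / X` — computed per parameter per true f,
#'   never on means.
#' * `coefficient_of_variation()`: `100 * SD(x) / mean(x)`, in percent.
#' * `overall_error()`: sum of the D and f relative errors,
#'   the scalar on which scheme recommendations are ranked.
#'
#' @param estimates Numeric vector of parameter estimates (one per noise
#'   realization); `NA`s dropped.
#' @param truth True parameter value (nonzero).
#' @param err_D,err_f Relative errors of D and f at matching
#'   (model, scheme, SNR, f).
#' @return A single numeric value (fraction, or percent for the CoV).
#' @examples
#' relative_bias(c(0.08, 0.08), 0.1)        # -0.2
#' relative_error(c(0.08, 0.08), 0.1)       # 0.2
#' coefficient_of_variation(c(1, 3))        # 50
#' overall_error(0.02, 0.10)                # 0.12
#' @name error_statistics
NULL

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname error_statistics
#' @export
relative_bias <- function(estimates, truth) {
  stopifnot(truth != 0)
  x <- estimates[!is.na(estimates)]
  mean(x - truth) / truth
}

#' @rdname error_statistics
#' @export
relative_error <- function(estimates, truth) {
  stopifnot(truth != 0)
  x <- estimates[!is.na(estimates)]
  sqrt(mean((x - truth)^2)) / truth
}

#' @rdname error_statistics
#' @export
coefficient_of_variation <- function(estimates) {
  x <- estimates[!is.na(estimates)]
  m <- mean(x)
  stopifnot(m != 0)
  100 * pop_sd(x) / m
}

#' @rdname error_statistics
#' @export
overall_error <- function(err_D, err_f) err_D + err_f

#' Aggregate a per-f statistic over the f grid
#'
#' The study's "value +/- value" convention: per-f statistics are averaged
#' over the simulated f grid and reported with the population SD across the
#' grid.
#'
#' @param x Numeric vector of per-f values (>= 2 points).
#' @return Named numeric `c(mean = , sd = )`.
#' @examples
#' aggregate_over_grid(c(1, 3))  # mean 2, sd 1
#' @export
aggregate_over_grid <- function(x) {
  stopifnot(length(x) >= 2L)
  c(mean = mean(x), sd = pop_sd(x))
}

#' Per-f error summary of a Monte-Carlo batch
#'
#' Computes relative bias, relative error and coefficient of variation of
#' the D and f estimates at every true f of a [run_monte_carlo()] batch,
#' excluding invalid fits.
#'
#' @param mc An `ivim_mc` object.
#' @return A tibble of class `ivim_errors`, one row per (parameter, f_true):
#'   columns `model`, `scheme`, `snr`, `calibration`, `parameter` (`"D"` or
#'   `"f"`), `f_true`, `truth`, `bias`, `relerr`, `cov` (percent),
#'   `n_valid`, `n_invalid`.
#' @examples
#' mc <- run_monte_carlo(tissue_models()[1, ], acquisition_scheme(500, 1000),
#'                       snr = 80, f_grid = c(0.1, 0.2), n_iter = 100, seed = 1)
#' summarize_errors(mc)
#' @export
summarize_errors <- function(mc) {
  stopifnot(inherits(mc, "ivim_mc"))
  D_true <- mc$model$D
  out <- mc$results |>
    dplyr::group_by(.data$f_true) |>
    dplyr::group_modify(function(d, key) {
      ok <- d$valid
      f <- key$f_true
      tibble::tibble(
        parameter = c("D", "f"),
        truth = c(D_true, f),
        bias = c(relative_bias(d$D_est[ok], D_true),
                 relative_bias(d$f_est[ok], f)),
        relerr = c(relative_error(d$D_est[ok], D_true),
                   relative_error(d$f_est[ok], f)),
        cov = c(coefficient_of_variation(d$D_est[ok]),
                coefficient_of_variation(d$f_est[ok])),
        n_valid = sum(ok),
        n_invalid = sum(!ok)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = mc$model$name, scheme = mc$scheme, snr = mc$snr,
                  calibration = mc$calibration, .before = 1)
  class(out) <- c("ivim_errors", class(out))
  out
}

#' Grid-level summary of per-f error statistics
#'
#' Aggregates an `ivim_errors` table over the f grid: mean +/- population SD
#' of bias, relative error and CoV per parameter, plus the overall relative
#' error (sum of the per-f D and f relative errors, then aggregated). A
#' first-order Monte-Carlo standard error of the grid-mean relative errors
#' (`relerr / sqrt(2 n)` per f, combined over the grid) is attached for
#' tie-breaking between schemes.
#'
#' @param errors An `ivim_errors` tibble from [summarize_errors()].
#' @return A one-row tibble per (model, scheme, snr): columns
#'   `bias_D_mean/sd`, `bias_f_mean/sd`, `relerr_D_mean/sd`,
#'   `relerr_f_mean/sd`, `cov_D_mean/sd`, `cov_f_mean/sd`,
#'   `overall_mean/sd`, `overall_se`, `n_invalid`.
#' @export
grid_summary <- function(errors) {
  stopifnot(is.data.frame(errors))
  errors |>
    dplyr::group_by(.data$model, .data$scheme, .data$snr, .data$calibration) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(
        dplyr::select(d, "parameter", "f_true", "bias", "relerr", "cov",
                      "n_valid", "n_invalid"),
        names_from = "parameter",
        values_from = c("bias", "relerr", "cov", "n_valid", "n_invalid")
      )
      ov <- overall_error(wide$relerr_D, wide$relerr_f)
      # per-f MC standard error of an RMS-type error: relerr / sqrt(2 n)
      se_f <- sqrt((wide$relerr_D / sqrt(2 * wide$n_valid_D))^2 +
                   (wide$relerr_f / sqrt(2 * wide$n_valid_f))^2)
      agg <- function(x) unname(aggregate_over_grid(x))
      tibble::tibble(
        bias_D_mean = agg(wide$bias_D)[1],  bias_D_sd = agg(wide$bias_D)[2],
        bias_f_mean = agg(wide$bias_f)[1],  bias_f_sd = agg(wide$bias_f)[2],
        relerr_D_mean = agg(wide$relerr_D)[1], relerr_D_sd = agg(wide$relerr_D)[2],
        relerr_f_mean = agg(wide$relerr_f)[1], relerr_f_sd = agg(wide$relerr_f)[2],
        cov_D_mean = agg(wide$cov_D)[1],    cov_D_sd = agg(wide$cov_D)[2],
        cov_f_mean = agg(wide$cov_f)[1],    cov_f_sd = agg(wide$cov_f)[2],
        overall_mean = agg(ov)[1],          overall_sd = agg(ov)[2],
        overall_se = sqrt(sum(se_f^2)) / length(se_f),
        n_invalid = sum(wide$n_invalid_D)
      )
    }) |>
    dplyr::ungroup()
}

#' Recommend b-value schemes from an error table
#'
#' For each (model, SNR) cell, ranks the candidate schemes by grid-mean
#' overall relative error. The recommended set is the argmin scheme together
#' with any scheme whose overall error is within the Monte-Carlo standard
#' error of the difference (ties are reported as ranges, as scheme optima
#' are often statistically indistinguishable). Schemes whose grid-mean f
#' relative error is below 10% are listed separately.
#'
#' @param grid_tbl A grid-level table from [grid_summary()] covering all
#'   candidate schemes (may span several models/SNRs).
#' @param criterion `"lowest_overall_error"` (default) or
#'   `"relerr_f_below_10pct"`; selects which scheme set fills the
#'   `recommended` column (the other is always reported too).
#' @return A tibble of class `ivim_recommendation`, one row per
#'   (model, snr): `best` (argmin scheme), `recommended` (comma-separated,
#'   incl. statistical ties or the <10% set), `under_10pct`,
#'   `overall_mean`, `overall_sd`, `relerr_f_mean`, `relerr_f_sd` (of the
#'   best scheme).
#' @export
recommend_scheme <- function(grid_tbl,
                             criterion = c("lowest_overall_error",
                                           "relerr_f_below_10pct")) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(grid_tbl) || nrow(grid_tbl) == 0L) {
    stop("`grid_tbl` must be a non-empty grid summary table", call. = FALSE)
  }
  out <- grid_tbl |>
    dplyr::group_by(.data$model, .data$snr) |>
    dplyr::group_modify(function(d, key) {
      i_best <- which.min(d$overall_mean)
      se_diff <- sqrt(d$overall_se^2 + d$overall_se[i_best]^2)
      tied <- d$overall_mean - d$overall_mean[i_best] < se_diff
      under <- d$scheme[d$relerr_f_mean < 0.10]
      rec <- if (criterion == "lowest_overall_error") d$scheme[tied] else under
      tibble::tibble(
        best = d$scheme[i_best],
        recommended = paste(rec, collapse = ", "),
        under_10pct = paste(under, collapse = ", "),
        overall_mean = d$overall_mean[i_best],
        overall_sd = d$overall_sd[i_best],
        relerr_f_mean = d$relerr_f_mean[i_best],
        relerr_f_sd = d$relerr_f_sd[i_best]
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("ivim_recommendation", class(out))
  attr(out, "criterion") <- criterion
  out
}
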
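#' Segmented (constrained) IVIM fit of D and f
#'
#' Two-step IVIM estimation from high b-values only: the nonzero fit
#' b-values are assumed free of perfusion signal, so `log(S)` is fitted
#' linearly in b (Eq. of the mono-exponential decay), giving
#' `D_est = -slope`; extrapolating the line to b = 0 gives the intercept
#' signal `S_int`, and the perfusion fraction follows from its offset to the
#' measured b = 0 signal, `f_est = 1 - S_int / S(0)`.
#'
#' With exactly two nonzero fit points the line is exact:
#' `D_est = log(S(b_low)/S(b_high)) / (b_high - b_low)`. With more points an
#' ordinary least-squares log-linear fit is used (in-vivo path).
#'
#' Estimates are deliberately not constrained: negative `D_est` (noise
#' inversion) or `f_est` outside \[0, 1\] are returned as-is so that
#' downstream bias/variance statistics are not censored. Only log-domain
#' failures (a required signal <= 0) invalidate a fit.
#'
#' @param curve A data frame with columns `b` and `signal` containing, at
#'   minimum, b = 0 and the scheme's fit b-values.
#' @param scheme An [acquisition_scheme()]; its nonzero fit b-values are
#'   `b_low ... b_high` drawn from `fit_pair` (two-point schemes) or, when
#'   `use_all` is `TRUE`, every nonzero b present in both the scheme and the
#'   curve.
#' @param use_all If `TRUE`, fit all nonzero b-values of the scheme found in
#'   the curve by least squares instead of the two `fit_pair` points.
#'
#' @return A one-row tibble: `D_est` (mm^2/s), `f_est`, `S_int`, `valid`.
#' @examples
#' brain <- tissue_model("brain", 0.7e-3, 7e-3)
#' curve <- make_signal_set(brain, f = 0.1)
#' segmented_fit(curve, acquisition_scheme(300, 1000))
#' @export
segmented_fit <- function(curve, scheme, use_all = FALSE) {
  stopifnot(is.data.frame(curve), all(c("b", "signal") %in% names(curve)))
  if (!inherits(scheme, "ivim_scheme")) stop("`scheme` must be an ivim_scheme", call. = FALSE)

  s0_idx <- which(curve$b == 0)
  if (length(s0_idx) == 0L) stop("curve must contain b = 0", call. = FALSE)
  S0 <- curve$signal[s0_idx[1]]

  fit_b <- if (use_all) {
    intersect(setdiff(scheme$b_values, 0), curve$b)
  } else {
    unname(scheme$fit_pair)
  }
  if (length(fit_b) < 2L) stop("need at least two nonzero fit b-values", call. = FALSE)
  idx <- match(fit_b, curve$b)
  if (anyNA(idx)) {
    stop("curve is missing fit b-values: ",
         paste(fit_b[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  S <- curve$signal[idx]

  if (S0 <= 0 || any(S <= 0)) {
    return(tibble::tibble(D_est = NA_real_, f_est = NA_real_,
                          S_int = NA_real_, valid = FALSE))
  }

  if (length(fit_b) == 2L) {
    res <- fit_two_point(S0, S[1], S[2], fit_b[1], fit_b[2])
    return(res)
  }
  # least-squares log-linear fit over >2 points
  co <- stats::coef(stats::lm(log(S) ~ fit_b))
  S_int <- exp(unname(co[1]))
  tibble::tibble(D_est = -unname(co[2]), f_est = 1 - S_int / S0,
                 S_int = S_int, valid = TRUE)
}

#' Vectorized two-point segmented fit
#'
#' Closed-form solution of the segmented fit when exactly two nonzero
#' b-values are acquired; vectorized over signal realizations (the workhorse
#' of the Monte-Carlo engine and the voxelwise fitter).
#'
#' @param S0 Measured signal at b = 0 (denominator of the perfusion
#'   fraction).
#' @param S_low,S_high Measured signals at `b_low` and `b_high`.
#' @param b_low,b_high The two fit b-values, s/mm^2.
#'
#' @return A tibble with one row per realization: `D_est`, `f_est`, `S_int`,
#'   `valid` (`FALSE` where any required signal was <= 0; estimates `NA`
#'   there).
#' @examples
#' fit_two_point(1, 0.74177, 0.44702, 300, 1000)
#' @export
fit_two_point <- function(S0, S_low, S_high, b_low, b_high) {
  stopifnot(b_high > b_low, b_low > 0)
  n <- max(length(S0), length(S_low), length(S_high))
  S0 <- rep_len(S0, n); S_low <- rep_len(S_low, n); S_high <- rep_len(S_high, n)
  valid <- S0 > 0 & S_low > 0 & S_high > 0
  D_est <- f_est <- S_int <- rep(NA_real_, n)
  if (any(valid)) {
    D <- log(S_low[valid] / S_high[valid]) / (b_high - b_low)
    Si <- exp(log(S_low[valid]) + b_low * D)
    D_est[valid] <- D
    S_int[valid] <- Si
    f_est[valid] <- 1 - Si / S0[valid]
  }
  tibble::tibble(D_est = D_est, f_est = f_est, S_int = S_int, valid = valid)
}

#' Noise-free intrinsic bias of the segmented fit
#'
#' The segmented fit applied to the exact bi-exponential curve: because the
#' perfusion compartment has not fully decayed at `b_low`, the high-b slope
#' is steepened (`D_est >= D`) and the intercept offset underestimates the
#' perfusion fraction (`f_est <= f`). This closed-form bias is the oracle
#' that Monte-Carlo runs converge to as SNR grows.
#'
#' @inheritParams ivim_signal
#' @param scheme An [acquisition_scheme()].
#' @return One-row tibble with `D_est`, `f_est`, `bias_D`, `bias_f`
#'   (relative, signed fractions).
#' @examples
#' intrinsic_bias(tissue_models()[1, ], f = 0.1, acquisition_scheme(300, 1000))
#' @export
intrinsic_bias <- function(model, f, scheme) {
  p <- as_model_params(model)
  bl <- scheme$fit_pair[["b_low"]]; bh <- scheme$fit_pair[["b_high"]]
  fit <- fit_two_point(1,
                       ivim_signal(model, f, bl),
                       ivim_signal(model, f, bh), bl, bh)
  dplyr::mutate(fit,
                bias_D = (.data$D_est - p$D) / p$D,
                bias_f = (.data$f_est - f) / f)
}
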
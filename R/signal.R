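#' Bi-exponential IVIM signal
#'
#' Normalized diffusion-weighted signal of the two-compartment IVIM model,
#'
#' \deqn{S(b)/S(0) = f e^{-b D^*} + (1 - f) e^{-b D},}
#'
#' where the perfusing (pseudo-diffusion) compartment carries fraction `f`
#' of the b = 0 signal and decays at rate `D_star`, and tissue water decays
#' at rate `D`.
#'
#' @param model A tissue model (one-row tibble from [tissue_model()] or any
#'   list with `D` and `D_star`).
#' @param f Perfusion fraction in \[0, 1\].
#' @param b b-value(s), s/mm^2, non-negative. Vectorized over `b`.
#'
#' @return Numeric vector of normalized signals in (0, 1\].
#' @examples
#' brain <- tissue_model("brain", 0.7e-3, 7e-3)
#' ivim_signal(brain, f = 0.1, b = c(0, 300, 500, 1000))
#' @export
ivim_signal <- function(model, f, b) {
  p <- as_model_params(model)
  if (!is.numeric(f) || any(f < 0 | f > 1)) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(b) || any(b < 0)) {
    stop("`b` must be non-negative", call. = FALSE)
  }
  f * exp(-b * p$D_star) + (1 - f) * exp(-b * p$D)
}

#' Noise-free signal set over a b-value grid
#'
#' Evaluates the IVIM signal for one (model, f) scenario at every b-value of
#' the generation grid, yielding the curve that noise is later added to.
#'
#' @inheritParams ivim_signal
#' @param b_grid b-values to generate, s/mm^2; defaults to
#'   [b_generation_grid()].
#'
#' @return A tibble with columns `b` and `signal`, carrying the generating
#'   truth (`D`, `D_star`, `f`) as attribute `"truth"`.
#' @examples
#' make_signal_set(tissue_models()[1, ], f = 0.1)
#' @export
make_signal_set <- function(model, f, b_grid = b_generation_grid()) {
  if (length(b_grid) == 0L) stop("`b_grid` must be non-empty", call. = FALSE)
  p <- as_model_params(model)
  curve <- tibble::tibble(b = as.numeric(b_grid),
                          signal = ivim_signal(model, f, b_grid))
  attr(curve, "truth") <- list(name = p$name, D = p$D, D_star = p$D_star, f = f)
  curve
}
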
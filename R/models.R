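#' Define an IVIM tissue model
#'
#' A tissue model is the ground-truth pair of decay rates of the
#' bi-exponential IVIM signal: the tissue diffusion coefficient `D` and the
#' perfusion-driven pseudo-diffusion coefficient `D_star`. The ratio
#' `D_star / D` indexes how separable the two compartments are: low ratios
#' (brain-like tissue) leave a perfusion residue in the high-b signal and
#' hence an intrinsic bias in the segmented fit, high ratios (liver-like)
#' make the high-b signal effectively mono-exponential.
#'
#' @param name Label for the model (e.g. `"brain"`).
#' @param D Tissue diffusion coefficient, mm^2/s. Must be positive.
#' @param D_star Pseudo-diffusion coefficient, mm^2/s. Must exceed `D`.
#'
#' @return A one-row tibble with columns `name`, `D`, `D_star`, `ratio`.
#' @examples
#' tissue_model("brain", D = 0.7e-3, D_star = 7e-3)
#' @export
tissue_model <- function(name, D, D_star) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    stop("`D` must be a single positive diffusion coefficient (mm^2/s)", call. = FALSE)
  }
  if (!is.numeric(D_star) || length(D_star) != 1L || D_star <= D) {
    stop("`D_star` must be a single value exceeding `D`", call. = FALSE)
  }
  tibble::tibble(name = name, D = D, D_star = D_star, ratio = D_star / D)
}

#' Canonical low/medium/high-perfusion tissue models
#'
#' The three reference perfusion scenarios used throughout the simulation
#' study: brain (low perfusion, D*/D = 10), kidney (medium, D*/D = 20) and
#' liver (high, D*/D = 70), all with D fixed at 0.7e-3 mm^2/s.
#'
#' @return A tibble with one row per model (columns as [tissue_model()]).
#' @examples
#' tissue_models()
#' @export
tissue_models <- function() {
  dplyr::bind_rows(
    tissue_model("brain",  D = 0.7e-3, D_star = 7e-3),
    tissue_model("kidney", D = 0.7e-3, D_star = 14e-3),
    tissue_model("liver",  D = 0.7e-3, D_star = 49e-3)
  )
}

#' Define a b-value acquisition scheme
#'
#' A scheme is the ordered list of acquired b-values together with the pair
#' of nonzero b-values `(b_low, b_high)` used in the segmented fit. The
#' rapid three-point protocol written `[300,1000]` acquires exactly
#' `{0, 300, 1000}` s/mm^2; schemes with additional b-values are accepted
#' for the voxelwise in-vivo path (the fit then uses least squares over all
#' nonzero fit b-values).
#'
#' @param b_low,b_high The two nonzero fit b-values, s/mm^2 (`b_low < b_high`).
#' @param b_values Acquired b-values; defaults to `c(0, b_low, b_high)`.
#'   Must contain 0 and both members of the fit pair.
#'
#' @return An object of class `ivim_scheme`: a list with `b_values`,
#'   `fit_pair` and a display `label` such as `"[300,1000]"`.
#' @examples
#' acquisition_scheme(500, 1000)
#' @export
acquisition_scheme <- function(b_low, b_high, b_values = c(0, b_low, b_high)) {
  stopifnot(is.numeric(b_low), is.numeric(b_high), length(b_low) == 1L,
            length(b_high) == 1L)
  if (!(b_low > 0 && b_high > b_low)) {
    stop("need 0 < b_low < b_high", call. = FALSE)
  }
  b_values <- sort(unique(as.numeric(b_values)))
  if (!0 %in% b_values) stop("`b_values` must contain b = 0", call. = FALSE)
  if (!all(c(b_low, b_high) %in% b_values)) {
    stop("both fit b-values must appear in `b_values`", call. = FALSE)
  }
  structure(
    list(
      b_values = b_values,
      fit_pair = c(b_low = b_low, b_high = b_high),
      label = sprintf("[%g,%g]", b_low, b_high)
    ),
    class = "ivim_scheme"
  )
}

#' @export
print.ivim_scheme <- function(x, ...) {
  cat("<ivim_scheme> ", x$label, "\n", sep = "")
  cat("  b-values: ", paste(x$b_values, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Candidate two-point fit schemes
#'
#' The eight rapid three-b-value protocols `[200,1000]` ... `[900,1000]`
#' evaluated by the simulation study.
#'
#' @param b_low Vector of lower fit b-values, s/mm^2.
#' @param b_high Upper fit b-value, s/mm^2.
#' @return A named list of [acquisition_scheme()] objects.
#' @examples
#' names(candidate_schemes())
#' @export
candidate_schemes <- function(b_low = seq(200, 900, by = 100), b_high = 1000) {
  schemes <- lapply(b_low, acquisition_scheme, b_high = b_high)
  names(schemes) <- vapply(schemes, `[[`, character(1), "label")
  schemes
}

#' Default b-value generation grid
#'
#' The ten b-values on which noise-free signal sets are generated before a
#' fit subset is selected: 0 and 200-1000 s/mm^2 in steps of 100.
#'
#' @return Numeric vector of b-values, s/mm^2.
#' @export
b_generation_grid <- function() c(0, seq(200, 1000, by = 100))

#' Default perfusion-fraction grid
#'
#' True f values simulated per tissue model: 0.06 to 0.30 in steps of 0.02
#' (13 values).
#'
#' @return Numeric vector of perfusion fractions.
#' @export
default_f_grid <- function() seq(0.06, 0.30, by = 0.02)

# Accept a tissue model given as one-row data frame / named list and return
# list(D=, D_star=, name=).
as_model_params <- function(model) {
  if (is.data.frame(model)) {
    if (nrow(model) != 1L) stop("`model` must be a single tissue model", call. = FALSE)
    model <- as.list(model)
  }
  if (!is.list(model) || is.null(model$D) || is.null(model$D_star)) {
    stop("`model` must have fields `D` and `D_star`", call. = FALSE)
  }
  list(name = model$name %||% "model", D = model$D, D_star = model$D_star)
}
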
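#' Voxelwise segmented IVIM fit of a DWI volume
#'
#' Applies the segmented fit to every masked voxel of a 4-D multi-b DWI
#' volume, producing D and f parameter maps. With a two-point scheme the
#' closed-form fit is fully vectorized; schemes with more nonzero b-values
#' use the least-squares log-linear path.
#'
#' @param dwi 4-D array (x, y, slice, b).
#' @param b_values b-values of the 4th dimension, s/mm^2 (must include 0 and
#'   all scheme fit b-values).
#' @param mask 3-D mask on the DWI grid: logical, or numeric treated as
#'   `> 0`. Voxels outside the mask are `NA` in the output maps.
#' @param scheme An [acquisition_scheme()].
#' @param use_all Fit all nonzero scheme b-values by least squares instead
#'   of the two-point pair.
#'
#' @return An `ivim_map`: list with 3-D arrays `D_est` (mm^2/s), `f_est`,
#'   `valid` (logical; `FALSE` where a required signal was <= 0), plus
#'   `scheme` and `n_fitted`.
#' @examples
#' set.seed(1)
#' s <- sample_subject(cohort_spec(n_subjects = 1))
#' map <- fit_voxelwise(s$dwi, s$b_values, s$gm_mask >= 0.7,
#'                      acquisition_scheme(500, 1000))
#' @export
fit_voxelwise <- function(dwi, b_values, mask, scheme, use_all = FALSE) {
  stopifnot(length(dim(dwi)) == 4L, dim(dwi)[4] == length(b_values))
  if (!inherits(scheme, "ivim_scheme")) stop("`scheme` must be an ivim_scheme", call. = FALSE)
  dims <- dim(dwi)[1:3]
  if (!all(dim(mask) == dims)) stop("mask grid does not match the DWI grid", call. = FALSE)
  mask <- if (is.logical(mask)) mask else mask > 0

  fit_b <- if (use_all) setdiff(scheme$b_values, 0) else unname(scheme$fit_pair)
  needed <- c(0, fit_b)
  idx_b <- match(needed, b_values)
  if (anyNA(idx_b)) {
    stop("DWI volume is missing b-values: ",
         paste(needed[is.na(idx_b)], collapse = ", "), call. = FALSE)
  }

  D_est <- f_est <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  vox <- which(mask)
  if (length(vox) > 0) {
    flat <- matrix(dwi, nrow = prod(dims))
    S <- flat[vox, idx_b, drop = FALSE]
    if (length(fit_b) == 2L) {
      fit <- fit_two_point(S[, 1], S[, 2], S[, 3], fit_b[1], fit_b[2])
    } else {
      fit <- dplyr::bind_rows(lapply(seq_along(vox), function(i) {
        segmented_fit(tibble::tibble(b = needed, signal = S[i, ]),
                      scheme, use_all = TRUE)
      }))
    }
    D_est[vox] <- fit$D_est
    f_est[vox] <- fit$f_est
    valid[vox] <- fit$valid
  }
  structure(list(D_est = D_est, f_est = f_est, valid = valid,
                 scheme = scheme$label, n_fitted = length(vox)),
            class = "ivim_map")
}

#' @export
print.ivim_map <- function(x, ...) {
  ok <- x$valid & !is.na(x$f_est)
  cat(sprintf("<ivim_map> scheme %s, %d voxels fitted (%d valid)\n",
              x$scheme, x$n_fitted, sum(ok)))
  if (any(ok)) {
    cat(sprintf("  mean D = %.3f x10^-3 mm^2/s, mean f = %.3f\n",
                1e3 * mean(x$D_est[ok]), mean(x$f_est[ok])))
  }
  invisible(x)
}

#' @method as_tibble ivim_map
#' @export
as_tibble.ivim_map <- function(x, ...) {
  dims <- dim(x$D_est)
  idx <- arrayInd(seq_along(x$D_est), dims)
  D_est <- as.vector(x$D_est)
  f_est <- as.vector(x$f_est)
  valid <- as.vector(x$valid)
  label <- x$scheme
  tibble::tibble(x = idx[, 1], y = idx[, 2], slice = idx[, 3],
                 D_est = D_est, f_est = f_est,
                 valid = valid, scheme = label) |>
    dplyr::filter(!is.na(D_est) | .data$valid)
}

# Bilinear resize of a 2-D matrix to target dimensions (pixel-center
# alignment, clamped at the border).
bilinear_resize <- function(mat, nx_t, ny_t) {
  nx <- nrow(mat); ny <- ncol(mat)
  sx <- (seq_len(nx_t) - 0.5) * nx / nx_t + 0.5
  sy <- (seq_len(ny_t) - 0.5) * ny / ny_t + 0.5
  x0 <- pmin(pmax(floor(sx), 1), nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(pmax(floor(sy), 1), ny); y1 <- pmin(y0 + 1, ny)
  wx <- pmin(pmax(sx - x0, 0), 1); wy <- pmin(pmax(sy - y0, 0), 1)
  m00 <- mat[x0, y0, drop = FALSE]; m10 <- mat[x1, y0, drop = FALSE]
  m01 <- mat[x0, y1, drop = FALSE]; m11 <- mat[x1, y1, drop = FALSE]
  WX <- matrix(wx, nx_t, ny_t); WY <- matrix(wy, nx_t, ny_t, byrow = TRUE)
  m00 * (1 - WX) * (1 - WY) + m10 * WX * (1 - WY) +
    m01 * (1 - WX) * WY + m11 * WX * WY
}

#' Resample a tissue mask onto the DWI grid
#'
#' Adjusts a (probabilistic or PVE) tissue mask to the in-plane size of the
#' acquired DWI images by slice-wise bilinear interpolation, then binarizes
#' at a threshold (default T = 0.7) to remove interpolation blurring at the
#' edges. On the PVE path only voxels with partial-volume value exactly 1
#' (pure tissue) are kept *before* resampling.
#'
#' @param mask 2-D matrix or 3-D array of mask values in \[0, 1\].
#' @param target_dim In-plane target size `c(nx, ny)`; slices are
#'   preserved. Defaults to the input size (threshold-only).
#' @param threshold Binarization threshold (default 0.7).
#' @param type `"probabilistic"` (default) or `"pve"`.
#' @return Logical mask of the target dimensions.
#' @examples
#' m <- matrix(0.8, 10, 10)
#' sum(resample_mask(m, c(5, 5)))  # all TRUE
#' @export
resample_mask <- function(mask, target_dim = NULL, threshold = 0.7,
                          type = c("probabilistic", "pve")) {
  type <- match.arg(type)
  nd <- length(dim(mask))
  if (is.null(dim(mask)) || !nd %in% c(2L, 3L)) {
    stop("`mask` must be a 2-D matrix or 3-D array", call. = FALSE)
  }
  if (type == "pve") mask[mask < 1] <- 0
  if (is.null(target_dim)) target_dim <- dim(mask)[1:2]
  stopifnot(length(target_dim) == 2L, all(target_dim >= 1))
  if (nd == 2L) {
    out <- bilinear_resize(mask, target_dim[1], target_dim[2])
    return(out >= threshold)
  }
  nz <- dim(mask)[3]
  out <- array(FALSE, c(target_dim, nz))
  for (k in seq_len(nz)) {
    out[, , k] <- bilinear_resize(mask[, , k], target_dim[1],
                                  target_dim[2]) >= threshold
  }
  out
}

#' Histogram specification by the square-root rule
#'
#' Fixes one common binning for all subjects and schemes: the number of bins
#' is the square root of the maximum number of ROI values across the
#' cohort (floored), and the bins span zero to the maximum observed value.
#'
#' @param max_n Maximum ROI voxel count across the cohort.
#' @param max_value Maximum parameter value observed (upper bin edge).
#' @return List of class `ivim_hist_spec` with `n_bins` and `breaks`.
#' @examples
#' histogram_spec(100, 0.4)  # 10 bins over [0, 0.4]
#' @export
histogram_spec <- function(max_n, max_value) {
  stopifnot(max_n >= 1, max_value > 0)
  n_bins <- max(1L, floor(sqrt(max_n)))
  structure(list(n_bins = n_bins,
                 breaks = seq(0, max_value, length.out = n_bins + 1L)),
            class = "ivim_hist_spec")
}

#' ROI histogram with fixed cohort-wide bins
#'
#' Bins parameter values on the fixed `[0, max]` grid of a
#' [histogram_spec()]. Values outside the range (possible for noisy
#' estimates under a spec fixed on another subset) are dropped.
#'
#' @param values Numeric vector of parameter values (non-empty).
#' @param spec An [histogram_spec()].
#' @return Tibble with `bin_mid`, `count`, `density`.
#' @export
roi_histogram <- function(values, spec) {
  stopifnot(inherits(spec, "ivim_hist_spec"))
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  br <- spec$breaks
  inside <- values >= br[1] & values <= br[length(br)]
  h <- graphics::hist(values[inside], breaks = br, plot = FALSE)
  tibble::tibble(bin_mid = h$mids, count = h$counts, density = h$density)
}

#' Cohort-average histogram
#'
#' Applies one [histogram_spec()] to each subject's values and averages the
#' per-subject counts without weighting.
#'
#' @param values_list List of numeric vectors (one per subject).
#' @param spec An [histogram_spec()]; by default derived from the data
#'   (square-root rule on the largest subject, range to the cohort maximum).
#' @return Tibble with `bin_mid`, `count` (mean across subjects).
#' @export
average_histogram <- function(values_list, spec = NULL) {
  stopifnot(is.list(values_list), length(values_list) >= 1L)
  if (is.null(spec)) {
    spec <- histogram_spec(max(lengths(values_list)),
                           max(unlist(values_list), na.rm = TRUE))
  }
  hs <- lapply(values_list, roi_histogram, spec = spec)
  tibble::tibble(bin_mid = hs[[1]]$bin_mid,
                 count = rowMeans(sapply(hs, `[[`, "count")))
}

#' Bland-Altman agreement between two measurement sets
#'
#' Mean paired difference (bias) and 95% limits of agreement
#' (`bias +/- 1.96 SD` of the differences).
#'
#' @param values_A,values_B Paired measurements (e.g. per-subject means
#'   under two b-value schemes).
#' @return One-row tibble: `bias`, `sd_diff`, `lower`, `upper`, `n`.
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 2.2, 3.1))
#' @export
bland_altman <- function(values_A, values_B) {
  stopifnot(length(values_A) == length(values_B), length(values_A) >= 1L)
  d <- values_A - values_B
  s <- if (length(d) > 1) stats::sd(d) else 0
  tibble::tibble(bias = mean(d), sd_diff = s,
                 lower = mean(d) - 1.96 * s, upper = mean(d) + 1.96 * s,
                 n = length(d))
}

#' Pearson correlation between paired measurements
#'
#' Product-moment correlation with its two-sided p-value and 95% CI.
#'
#' @param values_A,values_B Paired measurements (n >= 3).
#' @return One-row tibble: `r`, `p_value`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_r <- function(values_A, values_B) {
  stopifnot(length(values_A) == length(values_B), length(values_A) >= 3L)
  ct <- stats::cor.test(values_A, values_B, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
                 n = length(values_A))
}

#' Within-subject coefficient of variation (root-mean-square method)
#'
#' Scan-rescan repeatability across paired measurements:
#' `wCV = 100 * sqrt(mean((SD_pair / mean_pair)^2))`, where `SD_pair` is the
#' sample SD (n - 1 denominator, the repeatability convention for n = 2
#' replicates) and `mean_pair` the mean of each subject's repeated
#' measurements.
#'
#' @param data Data frame with one row per measurement.
#' @param value Column of measured values (tidy-eval).
#' @param subject Column identifying the repeated unit (subject, or
#'   subject-by-ROI) (tidy-eval).
#' @return One-row tibble: `wCV` (percent), `n_pairs`.
#' @examples
#' within_subject_cv(data.frame(id = c(1, 1), y = c(90, 110)), y, id)  # 14.1%
#' @export
within_subject_cv <- function(data, value, subject) {
  stopifnot(is.data.frame(data))
  pairs <- data |>
    dplyr::group_by({{ subject }}) |>
    dplyr::summarise(m = mean({{ value }}), s = stats::sd({{ value }}),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  if (nrow(pairs) == 0L) stop("need at least one subject with >= 2 measurements",
                              call. = FALSE)
  tibble::tibble(wCV = 100 * sqrt(mean((pairs$s / pairs$m)^2)),
                 n_pairs = nrow(pairs))
}

#' Compare parameter distributions under two masks
#'
#' Summarizes the D and f maps under a probabilistic mask (threshold rule)
#' and a PVE mask (pure-tissue rule): mean, median, 10th and 90th
#' percentiles, plus a Welch test for a difference of means between masks.
#'
#' @param map An `ivim_map`.
#' @param prob_mask,pve_mask Mask arrays in \[0, 1\] on the map grid.
#' @param threshold Binarization threshold for the probabilistic mask.
#' @return List with `summary` (tibble per mask x parameter) and `tests`
#'   (tibble per parameter with the Welch p-value).
#' @export
mask_comparison <- function(map, prob_mask, pve_mask, threshold = 0.7) {
  stopifnot(inherits(map, "ivim_map"))
  m_prob <- resample_mask(prob_mask, threshold = threshold)
  m_pve <- resample_mask(pve_mask, threshold = threshold, type = "pve")
  grab <- function(arr, m) {
    v <- arr[m & map$valid]
    v[!is.na(v)]
  }
  one <- function(mask_name, m) {
    purrr::map_dfr(list(D = map$D_est, f = map$f_est), function(arr) {
      v <- grab(arr, m)
      tibble::tibble(mean = mean(v), median = stats::median(v),
                     p10 = unname(stats::quantile(v, 0.10)),
                     p90 = unname(stats::quantile(v, 0.90)), n = length(v))
    }, .id = "parameter") |>
      dplyr::mutate(mask = mask_name, .before = 1)
  }
  tests <- purrr::map_dfr(list(D = map$D_est, f = map$f_est), function(arr) {
    tibble::tibble(p_value = stats::t.test(grab(arr, m_prob),
                                           grab(arr, m_pve))$p.value)
  }, .id = "parameter")
  list(summary = dplyr::bind_rows(one("probabilistic", m_prob),
                                  one("pve", m_pve)),
       tests = tests)
}
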
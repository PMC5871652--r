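#' Fit one subject's DWI with a scheme
#'
#' Convenience wrapper: binarizes the subject's probabilistic grey-matter
#' mask at the threshold (same grid, so resampling reduces to
#' thresholding), then fits voxelwise.
#'
#' @param subject An `ivim_subject`.
#' @param scheme An [acquisition_scheme()].
#' @param threshold Mask threshold (default 0.7).
#' @param acquisition 1 for the first scan, 2 for the repeat scan.
#' @return An `ivim_map`.
#' @export
fit_subject <- function(subject, scheme, threshold = 0.7, acquisition = 1) {
  stopifnot(inherits(subject, "ivim_subject"), acquisition %in% c(1, 2))
  dwi <- if (acquisition == 1) subject$dwi else subject$dwi_repeat
  if (is.null(dwi)) stop("subject has no repeat acquisition", call. = FALSE)
  mask <- resample_mask(subject$gm_mask, threshold = threshold)
  fit_voxelwise(dwi, subject$b_values, mask, scheme)
}

# Mean map value inside a roi_size x roi_size box centred at (cx, cy) on
# `slice`, intersected with the mask; NA when nothing valid falls inside.
roi_mean <- function(map_arr, valid, mask, cx, cy, slice, roi_size) {
  half <- roi_size %/% 2
  xr <- (cx - half + 1):(cx + half)
  yr <- (cy - half + 1):(cy + half)
  xr <- xr[xr >= 1 & xr <= dim(map_arr)[1]]
  yr <- yr[yr >= 1 & yr <= dim(map_arr)[2]]
  sel <- mask[xr, yr, slice] & valid[xr, yr, slice]
  v <- map_arr[xr, yr, slice][sel]
  if (length(v) == 0L) NA_real_ else mean(v, na.rm = TRUE)
}

# Default ROI centres: grey-matter centroid displaced up/down by the mean
# in-plane radius of the mask (the ring's mid-radius), so both boxes land
# on grey matter.
default_roi_centers <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cx <- round(mean(idx[, 1])); cy <- round(mean(idx[, 2]))
  r <- round(mean(sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)))
  list(c(cx, cy + r), c(cx, cy - r))
}

#' Cohort-level IVIM statistics
#'
#' Runs the full in-vivo-style analysis on a (synthetic or real) cohort for
#' two b-value schemes: voxelwise fits under the thresholded grey-matter
#' mask, per-subject mean parameters, Pearson correlation and Bland-Altman
#' agreement between the schemes, and scan-rescan repeatability (wCV by the
#' root-mean-square method) from the repeat-scan subjects using two
#' `roi_size` x `roi_size` ROIs per acquisition placed on the grey matter
#' (centroid +/- the mask's mean radius; configurable).
#'
#' @param cohort An `ivim_cohort`.
#' @param schemes List of two [acquisition_scheme()]s; agreement statistics
#'   are reported as scheme 1 minus scheme 2.
#' @param threshold Grey-matter mask threshold (default 0.7).
#' @param roi_size ROI edge length in voxels (default 4).
#' @param roi_centers Optional list of `c(x, y)` ROI centres; default
#'   placement as described above.
#'
#' @return An `ivim_cohort_stats`: list with tibbles `subject_means`
#'   (subject x scheme mean D/f), `correlation` and `bland_altman` (per
#'   parameter, scheme 1 vs scheme 2), and `repeatability` (wCV per scheme x
#'   parameter).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 4, n_repeat_subjects = 2,
#'                                       seed = 1))
#' stats <- cohort_stats(cohort)
#' stats$bland_altman
#' @export
cohort_stats <- function(cohort,
                         schemes = list(acquisition_scheme(300, 1000),
                                        acquisition_scheme(500, 1000)),
                         threshold = 0.7, roi_size = 4, roi_centers = NULL) {
  stopifnot(inherits(cohort, "ivim_cohort"), length(schemes) == 2L)
  labels <- vapply(schemes, `[[`, character(1), "label")

  subject_means <- purrr::map_dfr(cohort$subjects, function(s) {
    purrr::map_dfr(schemes, function(sc) {
      map <- fit_subject(s, sc, threshold = threshold)
      ok <- map$valid & !is.na(map$f_est)
      tibble::tibble(subject = s$id, scheme = sc$label,
                     mean_D = mean(map$D_est[ok]),
                     mean_f = mean(map$f_est[ok]),
                     n_vox = sum(ok))
    })
  })

  wide <- subject_means |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "scheme",
                       values_from = c("mean_D", "mean_f"))
  dA <- wide[[paste0("mean_D_", labels[1])]]
  dB <- wide[[paste0("mean_D_", labels[2])]]
  fA <- wide[[paste0("mean_f_", labels[1])]]
  fB <- wide[[paste0("mean_f_", labels[2])]]

  correlation <- dplyr::bind_rows(
    dplyr::mutate(pearson_r(dA, dB), parameter = "D", .before = 1),
    dplyr::mutate(pearson_r(fA, fB), parameter = "f", .before = 1)
  )
  ba <- dplyr::bind_rows(
    dplyr::mutate(bland_altman(dA, dB), parameter = "D", .before = 1),
    dplyr::mutate(bland_altman(fA, fB), parameter = "f", .before = 1)
  )

  repeat_subjects <- Filter(function(s) !is.null(s$dwi_repeat), cohort$subjects)
  repeatability <- NULL
  if (length(repeat_subjects) > 0) {
    roi_values <- purrr::map_dfr(repeat_subjects, function(s) {
      mask <- resample_mask(s$gm_mask, threshold = threshold)
      centers <- roi_centers %||% default_roi_centers(mask)
      slice <- ceiling(dim(mask)[3] / 2)
      purrr::map_dfr(schemes, function(sc) {
        purrr::map_dfr(1:2, function(acq) {
          map <- fit_subject(s, sc, threshold = threshold, acquisition = acq)
          purrr::imap_dfr(centers, function(ctr, k) {
            tibble::tibble(
              subject = s$id, scheme = sc$label, acquisition = acq, roi = k,
              D = roi_mean(map$D_est, map$valid, mask, ctr[1], ctr[2],
                           slice, roi_size),
              f = roi_mean(map$f_est, map$valid, mask, ctr[1], ctr[2],
                           slice, roi_size))
          })
        })
      })
    }) |>
      tidyr::pivot_longer(c("D", "f"), names_to = "parameter",
                          values_to = "value") |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::mutate(unit = paste(.data$subject, .data$roi, sep = "/"))
    repeatability <- roi_values |>
      dplyr::group_by(.data$scheme, .data$parameter) |>
      dplyr::group_modify(~ within_subject_cv(.x, .data$value, .data$unit)) |>
      dplyr::ungroup()
  }

  structure(list(subject_means = subject_means, correlation = correlation,
                 bland_altman = ba, repeatability = repeatability,
                 schemes = labels, threshold = threshold),
            class = "ivim_cohort_stats")
}

#' @export
print.ivim_cohort_stats <- function(x, ...) {
  cat(sprintf("<ivim_cohort_stats> schemes %s vs %s (differences: first minus second)\n",
              x$schemes[1], x$schemes[2]))
  means <- x$subject_means |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(D = mean(.data$mean_D), f = mean(.data$mean_f))
  for (i in seq_len(nrow(means))) {
    cat(sprintf("  %s: cohort mean D = %.3f x10^-3 mm^2/s, f = %.3f\n",
                means$scheme[i], 1e3 * means$D[i], means$f[i]))
  }
  cat(sprintf("  Bland-Altman bias: D %.4f x10^-3, f %.4f\n",
              1e3 * x$bland_altman$bias[x$bland_altman$parameter == "D"],
              x$bland_altman$bias[x$bland_altman$parameter == "f"]))
  if (!is.null(x$repeatability)) {
    r <- x$repeatability
    cat("  wCV (%):", paste(sprintf("%s %s %.1f", r$scheme, r$parameter, r$wCV),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
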
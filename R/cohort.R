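#' Synthetic grey-matter cohort specification
#'
#' Parameters of the volunteer-study stand-in: a cohort of subjects, each a
#' small multi-slice slab containing a ring-shaped grey-matter region with
#' voxelwise ground-truth IVIM parameters, three-b-value DWI signals at
#' realistic SNR, probabilistic and partial-volume (PVE) masks, and repeat
#' acquisitions for a subset of subjects.
#'
#' Ground-truth cohort means are for the *true* parameters, not the fitted
#' ones: with the segmented fit's intrinsic negative f bias at D*/D = 10, a
#' true grey-matter f around 0.15 yields fitted cohort means near 0.14
#' (`[500,1000]`) and 0.10-0.12 (`[300,1000]`), the range typical of adult
#' grey matter at 3 T. SNR is defined at b = 1000 (noise SD = mean
#' b = 1000 signal / snr) and the per-point noise SD is constant across b.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param n_repeat_subjects How many subjects carry a second, independently
#'   noisy acquisition of the same truth (default 4, capped at `n_subjects`).
#' @param grid_dim Image grid `c(nx, ny, n_slices)` (default 32 x 32 x 3).
#' @param gm_D_mean,gm_D_sd Between-subject distribution of the grey-matter
#'   mean diffusion coefficient, mm^2/s.
#' @param gm_f_mean,gm_f_sd Between-subject distribution of the grey-matter
#'   mean perfusion fraction.
#' @param voxel_D_sd,voxel_f_sd Within-subject voxelwise SDs.
#' @param ratio Voxelwise D*/D ratio (default 10, brain-like).
#' @param b_values Acquired b-values, s/mm^2 (default `{0, 300, 500, 1000}`).
#' @param snr SNR at b = 1000 (default 45).
#' @param seed Optional integer seed for [generate_cohort()].
#'
#' @return A list of class `ivim_cohort_spec`.
#' @examples
#' cohort_spec(n_subjects = 2, n_repeat_subjects = 1)
#' @export
cohort_spec <- function(n_subjects = 16,
                        n_repeat_subjects = min(4, n_subjects),
                        grid_dim = c(32, 32, 3),
                        gm_D_mean = 0.85e-3, gm_D_sd = 0.05e-3,
                        gm_f_mean = 0.15, gm_f_sd = 0.02,
                        voxel_D_sd = 0.1e-3, voxel_f_sd = 0.05,
                        ratio = 10, b_values = c(0, 300, 500, 1000),
                        snr = 45, seed = NULL) {
  stopifnot(n_subjects >= 1, n_repeat_subjects >= 0,
            n_repeat_subjects <= n_subjects,
            length(grid_dim) == 3, all(grid_dim[1:2] >= 16), grid_dim[3] >= 1,
            gm_D_sd >= 0, gm_f_sd >= 0, voxel_D_sd >= 0, voxel_f_sd >= 0,
            gm_D_mean > 0, gm_f_mean > 0, gm_f_mean < 1,
            ratio > 1, snr > 0, 0 %in% b_values, length(b_values) >= 3)
  structure(
    list(n_subjects = n_subjects, n_repeat_subjects = n_repeat_subjects,
         grid_dim = grid_dim,
         gm_D_mean = gm_D_mean, gm_D_sd = gm_D_sd,
         gm_f_mean = gm_f_mean, gm_f_sd = gm_f_sd,
         voxel_D_sd = voxel_D_sd, voxel_f_sd = voxel_f_sd,
         ratio = ratio, b_values = sort(unique(b_values)), snr = snr,
         seed = seed),
    class = "ivim_cohort_spec"
  )
}

# Truncated-normal draws by rejection; sd = 0 collapses to the mean.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Ring-shaped grey-matter probability and PVE maps for one slice geometry.
ring_masks <- function(grid_dim) {
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_in <- 0.22 * nx; r_out <- 0.42 * nx; w <- 1.5
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`))
  prob2d <- pmin(1, pmax(0, pmin((r - r_in) / w, (r_out - r) / w)))
  pve2d <- ifelse(r >= r_in + w & r <= r_out - w, 1, prob2d * 0.5)
  list(gm = array(rep(prob2d, nz), dim = grid_dim),
       pve = array(rep(pve2d, nz), dim = grid_dim))
}

#' Sample one synthetic subject
#'
#' Draws a subject's grey-matter mean parameters from the cohort
#' distributions, voxelwise truths (truncated normals: f in (0.01, 0.6),
#' D > 0.1e-3 mm^2/s) around them, evaluates the bi-exponential signal at
#' every acquired b-value and adds Gaussian noise with SD set so that the
#' empirical SNR at b = 1000 in grey matter matches the spec. `D_star` is
#' `ratio * D` per voxel.
#'
#' Uses the current RNG state; seed via [generate_cohort()] or `set.seed()`.
#'
#' @param spec A [cohort_spec()].
#' @param id Subject identifier.
#' @param with_repeat Add a second acquisition with independent noise.
#' @return An `ivim_subject`: list with `id`, `grid_dim`, `b_values`,
#'   truth arrays (`D`, `D_star`, `f`), masks (`gm_mask`, `pve_mask`),
#'   4-D `dwi` (x, y, slice, b), optional `dwi_repeat`, noise SD `sigma`,
#'   and the subject means drawn.
#' @examples
#' set.seed(1)
#' s <- sample_subject(cohort_spec(), id = "sub-01")
#' dim(s$dwi)
#' @export
sample_subject <- function(spec, id = "sub-01", with_repeat = FALSE) {
  stopifnot(inherits(spec, "ivim_cohort_spec"))
  dims <- spec$grid_dim
  nvox <- prod(dims)
  masks <- ring_masks(dims)

  subj_D <- rtrunc_norm(1, spec$gm_D_mean, spec$gm_D_sd, lower = 0.1e-3)
  subj_f <- rtrunc_norm(1, spec$gm_f_mean, spec$gm_f_sd,
                        lower = 0.01, upper = 0.6)
  D <- array(rtrunc_norm(nvox, subj_D, spec$voxel_D_sd, lower = 0.1e-3), dims)
  f <- array(rtrunc_norm(nvox, subj_f, spec$voxel_f_sd,
                         lower = 0.01, upper = 0.6), dims)
  D_star <- spec$ratio * D

  nb <- length(spec$b_values)
  clean <- array(0, c(dims, nb))
  for (j in seq_len(nb)) {
    b <- spec$b_values[j]
    clean[, , , j] <- f * exp(-b * D_star) + (1 - f) * exp(-b * D)
  }
  gm <- masks$pve == 1
  b_max <- which.max(spec$b_values)
  sigma <- mean(clean[, , , b_max][gm]) / spec$snr

  noisy <- function() clean + array(stats::rnorm(length(clean), 0, sigma),
                                    dim = dim(clean))
  structure(
    list(id = id, grid_dim = dims, b_values = spec$b_values,
         truth = list(D = D, D_star = D_star, f = f,
                      subject_mean_D = subj_D, subject_mean_f = subj_f),
         gm_mask = masks$gm, pve_mask = masks$pve,
         dwi = noisy(),
         dwi_repeat = if (with_repeat) noisy() else NULL,
         sigma = sigma),
    class = "ivim_subject"
  )
}

#' @export
print.ivim_subject <- function(x, ...) {
  cat(sprintf("<ivim_subject> %s  grid %s  b = {%s}%s\n", x$id,
              paste(x$grid_dim, collapse = "x"),
              paste(x$b_values, collapse = ", "),
              if (!is.null(x$dwi_repeat)) "  (+ repeat scan)" else ""))
  invisible(x)
}

#' Generate a synthetic volunteer cohort
#'
#' Samples `n_subjects` subjects under one seed; the first
#' `n_repeat_subjects` of them carry a repeat acquisition (identical truth,
#' independent noise) for repeatability analysis.
#'
#' @param spec A [cohort_spec()].
#' @return An `ivim_cohort`: list with `subjects` (list of
#'   `ivim_subject`) and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 2, n_repeat_subjects = 1,
#'                                       seed = 1))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ivim_cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    sample_subject(spec, id = sprintf("sub-%02d", i),
                   with_repeat = i <= spec$n_repeat_subjects)
  })
  structure(list(subjects = subjects, spec = spec), class = "ivim_cohort")
}

#' @export
print.ivim_cohort <- function(x, ...) {
  cat(sprintf("<ivim_cohort> %d subjects (%d with repeat scans), grid %s, SNR %g at b = %g\n",
              length(x$subjects), x$spec$n_repeat_subjects,
              paste(x$spec$grid_dim, collapse = "x"), x$spec$snr,
              max(x$spec$b_values)))
  invisible(x)
}

#' Write a cohort to disk in standard imaging formats
#'
#' Per subject: 4-D DWI NIfTI (`<id>_dwi.nii`, plus `_dwi2.nii` for repeat
#' acquisitions), 3-D mask NIfTIs (`_gm.nii`, `_pve.nii`), an FSL-style
#' `.bval` text file, and a JSON truth sidecar with the subject-mean ground
#' truth — so downstream fitting consumes synthetic and real data through
#' the same files.
#'
#' @param cohort An `ivim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    base <- file.path(dir, s$id)
    RNifti::writeNifti(RNifti::asNifti(s$dwi), paste0(base, "_dwi.nii"))
    if (!is.null(s$dwi_repeat)) {
      RNifti::writeNifti(RNifti::asNifti(s$dwi_repeat), paste0(base, "_dwi2.nii"))
    }
    RNifti::writeNifti(RNifti::asNifti(s$gm_mask), paste0(base, "_gm.nii"))
    RNifti::writeNifti(RNifti::asNifti(s$pve_mask), paste0(base, "_pve.nii"))
    writeLines(paste(s$b_values, collapse = " "), paste0(base, ".bval"))
    jsonlite::write_json(
      list(id = s$id, synthetic = TRUE,
           subject_mean_D = s$truth$subject_mean_D,
           subject_mean_f = s$truth$subject_mean_f,
           ratio = cohort$spec$ratio, sigma = s$sigma,
           snr = cohort$spec$snr),
      paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an FSL-style b-value file
#'
#' @param path Path to a whitespace-separated `.bval` text file.
#' @return Numeric vector of b-values.
#' @export
read_bval <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}
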
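spec_small <- function(...) {
  cohort_spec(n_subjects = 4, n_repeat_subjects = 2, grid_dim = c(24, 24, 2), ...)
}

test_that("zero-variance spec collapses every voxel to the cohort means", {
  spec <- spec_small(gm_D_sd = 0, gm_f_sd = 0, voxel_D_sd = 0, voxel_f_sd = 0,
                     seed = 1)
  s <- generate_cohort(spec)$subjects[[1]]
  expect_true(all(s$truth$D == spec$gm_D_mean))
  expect_true(all(s$truth$f == spec$gm_f_mean))
  expect_true(all(s$truth$D_star == spec$ratio * spec$gm_D_mean))
})

test_that("cohort truth recovers the specified distributions", {
  spec <- cohort_spec(n_subjects = 16, n_repeat_subjects = 0,
                      grid_dim = c(24, 24, 1), seed = 3)
  cohort <- generate_cohort(spec)
  subj_f <- vapply(cohort$subjects, function(s) s$truth$subject_mean_f, numeric(1))
  se <- spec$gm_f_sd / sqrt(16)
  expect_lt(abs(mean(subj_f) - spec$gm_f_mean), 3 * se)
  subj_D <- vapply(cohort$subjects, function(s) s$truth$subject_mean_D, numeric(1))
  expect_lt(abs(mean(subj_D) - spec$gm_D_mean), 3 * spec$gm_D_sd / sqrt(16))
  # truncation bounds respected voxelwise
  allf <- unlist(lapply(cohort$subjects, function(s) s$truth$f))
  expect_true(all(allf > 0.01 & allf < 0.6))
})

test_that("repeat acquisitions share truth and differ only in noise", {
  cohort <- generate_cohort(spec_small(seed = 4))
  with_rep <- Filter(function(s) !is.null(s$dwi_repeat), cohort$subjects)
  expect_length(with_rep, 2)
  s <- with_rep[[1]]
  expect_false(identical(s$dwi, s$dwi_repeat))
  # identical truth: both acquisitions are the same clean signal + noise,
  # so their difference is pure noise with SD sqrt(2) * sigma
  d <- s$dwi - s$dwi_repeat
  expect_equal(sd(d), sqrt(2) * s$sigma, tolerance = 0.05)
  expect_equal(mean(d), 0, tolerance = 4 * s$sigma / sqrt(length(d) / 2))
})

test_that("cohorts are deterministic under a seed and SNR lands at spec", {
  a <- generate_cohort(spec_small(seed = 7))
  b <- generate_cohort(spec_small(seed = 7))
  expect_identical(a$subjects[[3]]$dwi, b$subjects[[3]]$dwi)
  # empirical SNR at b = 1000 in pure grey matter
  s <- a$subjects[[1]]
  gm <- s$pve_mask == 1
  j <- which(s$b_values == 1000)
  snr_emp <- mean(s$dwi[, , , j][gm]) / s$sigma
  expect_equal(snr_emp, a$spec$snr, tolerance = 0.1)
})

test_that("fitted cohort shows the scheme ordering the bias oracle predicts", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 6, n_repeat_subjects = 0,
                                        grid_dim = c(24, 24, 2), seed = 5))
  means <- purrr::map_dfr(cohort$subjects, function(s) {
    purrr::map_dfr(list(acquisition_scheme(300, 1000), acquisition_scheme(500, 1000)),
                   function(sc) {
      map <- fit_subject(s, sc)
      ok <- map$valid
      tibble::tibble(scheme = sc$label, f = mean(map$f_est[ok]),
                     D = mean(map$D_est[ok]), f_true = mean(s$truth$f))
    })
  })
  m300 <- means[means$scheme == "[300,1000]", ]
  m500 <- means[means$scheme == "[500,1000]", ]
  expect_true(all(m500$f > m300$f))
  expect_true(all(m300$D > m500$D))
  # [500,1000] recovers truth minus its (smaller) intrinsic bias
  expect_true(all(m500$f < m300$f_true))
})

test_that("Bland-Altman bias between schemes is negative and grows with cohort f", {
  ba_at <- function(fmean, seed) {
    cohort <- generate_cohort(cohort_spec(n_subjects = 6, n_repeat_subjects = 0,
                                          grid_dim = c(24, 24, 2),
                                          gm_f_mean = fmean, seed = seed))
    st <- cohort_stats(cohort)
    st$bland_altman$bias[st$bland_altman$parameter == "f"]
  }
  lo <- ba_at(0.10, 6)
  hi <- ba_at(0.25, 6)
  expect_lt(lo, 0)
  expect_lt(hi, 0)
  expect_gt(abs(hi), abs(lo))
})

test_that("cohort files round-trip through NIfTI/bval/JSON", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(n_subjects = 2, n_repeat_subjects = 1,
                                        grid_dim = c(16, 16, 1), seed = 8))
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "sub-01_dwi.nii")))
  expect_true(file.exists(file.path(dir, "sub-01_dwi2.nii")))
  expect_false(file.exists(file.path(dir, "sub-02_dwi2.nii")))
  bv <- read_bval(file.path(dir, "sub-02.bval"))
  expect_equal(bv, c(0, 300, 500, 1000))
  vol <- RNifti::readNifti(file.path(dir, "sub-01_dwi.nii"))
  expect_equal(dim(vol), c(16, 16, 1, 4))
  expect_equal(as.array(vol), cohort$subjects[[1]]$dwi, tolerance = 1e-6,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "sub-01_truth.json"))
  expect_true(truth$synthetic)
})

test_that("cohort-average f histogram sits higher for [500,1000] than [300,1000]", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 8, n_repeat_subjects = 0,
                                        seed = 9))
  vals <- function(sc) {
    lapply(cohort$subjects, function(s) {
      map <- fit_subject(s, sc)
      map$f_est[map$valid & !is.na(map$f_est)]
    })
  }
  v300 <- vals(acquisition_scheme(300, 1000))
  v500 <- vals(acquisition_scheme(500, 1000))
  spec <- histogram_spec(max(lengths(c(v300, v500))),
                         max(unlist(c(v300, v500))))
  h300 <- average_histogram(v300, spec)
  h500 <- average_histogram(v500, spec)
  mode300 <- h300$bin_mid[which.max(h300$count)]
  mode500 <- h500$bin_mid[which.max(h500$count)]
  expect_gte(mode500, mode300)
  wmean <- function(h) sum(h$bin_mid * h$count) / sum(h$count)
  expect_gt(wmean(h500), wmean(h300))
})
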
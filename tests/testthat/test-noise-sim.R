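test_that("signal sets evaluate the bi-exponential model on the generation grid", {
  brain <- brain_model()
  curve <- make_signal_set(brain, 0.1)
  expect_equal(curve$b, c(0, seq(200, 1000, 100)))
  expect_equal(curve$signal[curve$b == 300], 0.7418, tolerance = 1e-4)
  expect_equal(curve$signal[curve$b == 500], 0.63724, tolerance = 1e-5)
  expect_equal(curve$signal[curve$b == 1000], 0.44702, tolerance = 1e-5)
  # liver, f = 0.3 at b = 1000: perfusion term ~ e^-49, negligible
  liver <- liver_model()
  expect_equal(ivim_signal(liver, 0.3, 1000), 0.7 * exp(-0.7), tolerance = 1e-5)
  truth <- attr(curve, "truth")
  expect_equal(truth$f, 0.1)
})

test_that("noise calibrations give the documented sigmas", {
  curve <- make_signal_set(brain_model(), 0.1)
  expect_equal(noise_sigma(curve, 40), 0.006655, tolerance = 1e-3)
  expect_equal(noise_sigma(curve, 80), 6.655e-5, tolerance = 1e-3)
  expect_equal(noise_sigma(curve, 40, "b0_linear"), 0.025)
  # rms_db sigma halves-ish per +6 dB; exact ratio is 10^(15/20) from 40 to 55
  expect_equal(noise_sigma(curve, 40) / noise_sigma(curve, 55), 10^(15 / 20))
})

test_that("added noise is zero-mean with the requested SD, on every point incl. b = 0", {
  curve <- make_signal_set(brain_model(), 0.1)
  expect_identical(add_noise(curve, 0), curve)
  set.seed(5)
  n <- 1e5
  sigma <- 0.02
  noisy <- matrix(rnorm(n * 2, 0, sigma), ncol = 2)
  s0 <- curve$signal[curve$b == 0] + noisy[, 1]
  s1000 <- curve$signal[curve$b == 1000] + noisy[, 2]
  expect_equal(mean(s0), 1, tolerance = 4 * sigma / sqrt(n))
  expect_equal(sd(s1000), sigma, tolerance = 0.02)
  # add_noise itself perturbs b = 0 too
  set.seed(6)
  pert <- add_noise(curve, 0.05)
  expect_false(pert$signal[pert$b == 0] == 1)
})

test_that("Monte-Carlo batches are reproducible and structured as promised", {
  brain <- brain_model()
  sc <- acquisition_scheme(300, 1000)
  a <- run_monte_carlo(brain, sc, snr = 55, f_grid = c(0.1, 0.2), n_iter = 50, seed = 9)
  b <- run_monte_carlo(brain, sc, snr = 55, f_grid = c(0.1, 0.2), n_iter = 50, seed = 9)
  expect_identical(a$results, b$results)
  expect_equal(nrow(a$results), 2 * 50)
  expect_equal(unique(a$results$f_true), c(0.1, 0.2))
  # different seed, different draws
  c_ <- run_monte_carlo(brain, sc, snr = 55, f_grid = c(0.1, 0.2), n_iter = 50, seed = 10)
  expect_false(identical(a$results$f_est, c_$results$f_est))
})

test_that("batch means converge to the noise-free oracle at high SNR", {
  brain <- brain_model()
  for (bl in c(300, 500)) {
    mc <- run_monte_carlo(brain, acquisition_scheme(bl, 1000), snr = 120,
                          f_grid = c(0.1, 0.3), n_iter = 400, seed = 2)
    for (f in c(0.1, 0.3)) {
      orc <- oracle_noise_free(0.7e-3, 7e-3, f, bl, 1000)
      got <- mc$results[mc$results$f_true == f, ]
      expect_equal(mean(got$f_est), orc$f_est, tolerance = 2e-3)
      expect_equal(mean(got$D_est), orc$D_est, tolerance = 2e-3)
    }
  }
})

test_that("noise-driven non-positive signals are dropped, counted and warned about", {
  brain <- brain_model()
  expect_warning(
    mc <- run_monte_carlo(brain, acquisition_scheme(900, 1000), snr = 10,
                          f_grid = c(0.3), n_iter = 400, seed = 4),
    "invalid"
  )
  expect_gt(sum(!mc$results$valid), 0)
  expect_true(all(is.na(mc$results$D_est[!mc$results$valid])))
})

test_that("Monte-Carlo dispersion matches first-order error propagation at small noise", {
  brain <- brain_model()
  for (bl in c(300, 500)) {
    for (snr in c(55, 80)) {
      mc <- run_monte_carlo(brain, acquisition_scheme(bl, 1000), snr = snr,
                            f_grid = c(0.1, 0.2), n_iter = 2000, seed = 21)
      for (f in c(0.1, 0.2)) {
        sigma <- mc$sigma$sigma[mc$sigma$f_true == f]
        got <- mc$results[mc$results$f_true == f, ]
        expect_equal(sd(got$f_est), delta_sd_f(0.7e-3, 7e-3, f, bl, 1000, sigma),
                     tolerance = 0.1)
        expect_equal(sd(got$D_est), delta_sd_D(0.7e-3, 7e-3, f, bl, 1000, sigma),
                     tolerance = 0.1)
      }
    }
  }
})

test_that("per-f CoV of f falls with SNR and rises with b_low", {
  brain <- brain_model()
  fg <- c(0.1, 0.2)
  cov_at <- function(bl, snr) {
    mc <- run_monte_carlo(brain, acquisition_scheme(bl, 1000), snr = snr,
                          f_grid = fg, n_iter = 600, seed = 31)
    s <- summarize_errors(mc)
    s$cov[s$parameter == "f"]
  }
  by_snr <- sapply(c(40, 55, 80), function(snr) cov_at(300, snr))
  expect_true(all(by_snr[, 1] > by_snr[, 2]))
  expect_true(all(by_snr[, 2] > by_snr[, 3]))
  by_bl <- sapply(c(300, 500, 800), function(bl) cov_at(bl, 40))
  expect_true(all(by_bl[, 1] < by_bl[, 2]))
  expect_true(all(by_bl[, 2] < by_bl[, 3]))
})
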
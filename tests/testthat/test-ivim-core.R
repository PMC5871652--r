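test_that("bi-exponential signal obeys its limits and a spot value", {
  brain <- brain_model()
  # normalization at b = 0, any parameters
  for (f in c(0, 0.1, 0.5, 1)) expect_identical(ivim_signal(brain, f, 0), 1)
  # mono-exponential limit at f = 0
  b <- c(100, 500, 1000)
  expect_equal(ivim_signal(brain, 0, b), exp(-b * 0.7e-3))
  # direct evaluation, brain scenario
  expect_equal(ivim_signal(brain, 0.1, 1000), 0.44702, tolerance = 1e-5)
  expect_equal(ivim_signal(brain, 0.1, c(300, 500)),
               c(0.74177, 0.63724), tolerance = 1e-5)
  # signals strictly decreasing in b, in (0, 1]
  s <- ivim_signal(brain, 0.2, seq(0, 1000, by = 100))
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("signal inputs are validated", {
  brain <- brain_model()
  expect_error(ivim_signal(brain, -0.1, 100), "f")
  expect_error(ivim_signal(brain, 1.2, 100), "f")
  expect_error(ivim_signal(brain, 0.1, -5), "b")
  expect_error(tissue_model("x", -1e-3, 7e-3), "D")
  expect_error(tissue_model("x", 0.7e-3, 0.5e-3), "D_star")
  expect_error(acquisition_scheme(1000, 300))
  expect_error(acquisition_scheme(300, 1000, b_values = c(300, 1000)), "b = 0")
  expect_error(make_signal_set(brain, 0.1, numeric(0)), "non-empty")
})

test_that("segmented fit is exact for mono-exponential input on every scheme", {
  brain <- brain_model()
  for (sc in candidate_schemes()) {
    fit <- segmented_fit(make_signal_set(brain, 0), sc)
    expect_equal(fit$D_est, 0.7e-3, tolerance = 1e-12)
    expect_equal(fit$f_est, 0, tolerance = 1e-12)
    expect_true(fit$valid)
  }
})

test_that("segmented fit matches the linear-solve oracle on noise-free curves", {
  brain <- brain_model()
  fit <- segmented_fit(make_signal_set(brain, 0.1), acquisition_scheme(300, 1000))
  expect_equal(fit$D_est, 7.235e-4, tolerance = 1e-4)
  expect_equal(fit$f_est, 0.0784, tolerance = 1e-3)
  fit5 <- segmented_fit(make_signal_set(brain, 0.1), acquisition_scheme(500, 1000))
  expect_equal(fit5$f_est, 0.0916, tolerance = 1e-3)
  # random scenarios against the independent solve-based oracle
  set.seed(11)
  for (i in 1:25) {
    D <- runif(1, 0.3e-3, 2e-3)
    Ds <- D * runif(1, 5, 80)
    f <- runif(1, 0.02, 0.4)
    bl <- sample(seq(200, 900, 100), 1)
    m <- tissue_model("x", D, Ds)
    fit <- segmented_fit(make_signal_set(m, f), acquisition_scheme(bl, 1000))
    orc <- oracle_noise_free(D, Ds, f, bl, 1000)
    expect_equal(fit$D_est, orc$D_est, tolerance = 1e-12)
    expect_equal(fit$f_est, orc$f_est, tolerance = 1e-12)
  }
})

test_that("two-point closed form equals the least-squares path to machine precision", {
  brain <- brain_model()
  sc <- acquisition_scheme(300, 1000)
  set.seed(3)
  for (i in 1:10) {
    curve <- add_noise(make_signal_set(brain, 0.15, c(0, 300, 1000)), 0.01)
    a <- segmented_fit(curve, sc)
    b <- segmented_fit(curve, sc, use_all = TRUE)  # lm() route, same 2 points
    expect_equal(a$D_est, b$D_est, tolerance = 1e-12)
    expect_equal(a$f_est, b$f_est, tolerance = 1e-12)
  }
})

test_that("perfusion residue vanishes for liver at high b_low", {
  liver <- liver_model()
  for (f in c(0.1, 0.3)) {
    fit <- segmented_fit(make_signal_set(liver, f), acquisition_scheme(800, 1000))
    expect_equal(fit$D_est, 0.7e-3, tolerance = 1e-3)  # within 0.1%
    expect_equal(fit$f_est, f, tolerance = 1e-3)
  }
})

test_that("degenerate signals invalidate the fit; estimates are never clamped", {
  sc <- acquisition_scheme(300, 1000)
  bad <- tibble::tibble(b = c(0, 300, 1000), signal = c(1, -0.01, 0.4))
  fit <- segmented_fit(bad, sc)
  expect_false(fit$valid)
  expect_true(is.na(fit$D_est))
  # S(b_low) < S(b_high): negative D_est returned as-is
  inv <- tibble::tibble(b = c(0, 300, 1000), signal = c(1, 0.4, 0.5))
  fit <- segmented_fit(inv, sc)
  expect_true(fit$valid)
  expect_lt(fit$D_est, 0)
  # vectorized path flags only the offending realizations
  v <- fit_two_point(c(1, 1), c(0.7, -0.1), c(0.45, 0.45), 300, 1000)
  expect_identical(v$valid, c(TRUE, FALSE))
})

test_that("intrinsic f bias is negative, D bias positive, and |f bias| shrinks with b_low", {
  models <- list(brain_model(), kidney_model(), liver_model())
  for (m in models) {
    for (sc in candidate_schemes()) {
      for (f in c(0.06, 0.18, 0.30)) {
        ib <- intrinsic_bias(m, f, sc)
        # float-level slack: the liver residue is ~1e-16 at high b_low
        expect_lte(ib$f_est, f + 1e-12)
        expect_gte(ib$D_est, m$D - 1e-12)
      }
    }
  }
  # monotone decay of |f bias| with b_low (brain, f = 0.1)
  bias <- vapply(seq(200, 900, 100), function(bl) {
    abs(intrinsic_bias(brain_model(), 0.1, acquisition_scheme(bl, 1000))$bias_f)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})
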
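# Independent oracles kept deliberately separate from the package's code
# paths: the two-point fit is re-derived by solving the 2x2 linear system
# for the log-linear line, and estimator dispersion is predicted by
# first-order (delta-method) error propagation.

# Bi-exponential signal, written out directly.
oracle_signal <- function(D, D_star, f, b) {
  f * exp(-b * D_star) + (1 - f) * exp(-b * D)
}

# Segmented fit through two points via an explicit linear solve of
# log S = intercept + slope * b.
oracle_two_point <- function(S0, S_low, S_high, b_low, b_high) {
  co <- solve(rbind(c(1, b_low), c(1, b_high)), c(log(S_low), log(S_high)))
  S_int <- exp(co[1])
  list(D_est = -co[2], f_est = 1 - S_int / S0, S_int = S_int)
}

# Noise-free segmented-fit estimates for a (D, D_star, f) scenario.
oracle_noise_free <- function(D, D_star, f, b_low, b_high) {
  oracle_two_point(1,
                   oracle_signal(D, D_star, f, b_low),
                   oracle_signal(D, D_star, f, b_high),
                   b_low, b_high)
}

# First-order SD of the f estimate under iid Gaussian noise of SD `sigma`
# on the three measured signals. With a = b_high/(b_high - b_low) and
# c = b_low/(b_high - b_low), log S_int = a log S_low - c log S_high, so
# Var(f) ~ (S_int/S0)^2 [ (a s/S_low)^2 + (c s/S_high)^2 + (s/S0)^2 ].
delta_sd_f <- function(D, D_star, f, b_low, b_high, sigma) {
  S0 <- 1
  Sl <- oracle_signal(D, D_star, f, b_low)
  Sh <- oracle_signal(D, D_star, f, b_high)
  a <- b_high / (b_high - b_low)
  cc <- b_low / (b_high - b_low)
  Sint <- exp(a * log(Sl) - cc * log(Sh))
  (Sint / S0) * sqrt((a * sigma / Sl)^2 + (cc * sigma / Sh)^2 +
                       (sigma / S0)^2)
}

# First-order SD of the D estimate: Var(D) ~ s^2 (1/Sl^2 + 1/Sh^2) /
# (b_high - b_low)^2.
delta_sd_D <- function(D, D_star, f, b_low, b_high, sigma) {
  Sl <- oracle_signal(D, D_star, f, b_low)
  Sh <- oracle_signal(D, D_star, f, b_high)
  sqrt(sigma^2 * (1 / Sl^2 + 1 / Sh^2)) / (b_high - b_low)
}

brain_model <- function() tissue_model("brain", 0.7e-3, 7e-3)
kidney_model <- function() tissue_model("kidney", 0.7e-3, 14e-3)
liver_model <- function() tissue_model("liver", 0.7e-3, 49e-3)
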
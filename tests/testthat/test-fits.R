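test_that("noiseless binding isotherms are recovered exactly", {
  fp <- simulate_fp_titration(kd = 2.0, noise_sd = 0)
  fit <- fit_fp_binding(fp$conc, fp$polarization)
  expect_equal(fit$kd, 2.0, tolerance = 1e-6)
  expect_equal(fit$p_free, 50, tolerance = 1e-6)
  expect_equal(fit$p_bound, 150, tolerance = 1e-6)
  ## at [T] = Kd the fitted curve passes through the half-saturation point
  mid <- fit$p_free + (fit$p_bound - fit$p_free) * fit$kd / (fit$kd + fit$kd)
  expect_equal(mid, (fit$p_free + fit$p_bound) / 2, tolerance = 1e-9)
})

test_that("Kd fitting is scale-equivariant and depletion-aware", {
  fp <- simulate_fp_titration(kd = 3.1, noise_sd = 0)
  f1 <- fit_fp_binding(fp$conc, fp$polarization)
  f10 <- fit_fp_binding(fp$conc * 10, fp$polarization)
  expect_equal(f10$kd, 10 * f1$kd, tolerance = 1e-6)
  ## at 10 nM tracer and micromolar Kd the exact-depletion model agrees < 0.5%
  fq <- fit_fp_binding(fp$conc, fp$polarization, model = "quadratic_depletion")
  expect_lt(abs(fq$kd - f1$kd) / f1$kd, 0.005)
})

test_that("Monte-Carlo Kd recovery is unbiased with calibrated intervals", {
  kds <- numeric(100)
  covered <- logical(100)
  for (i in 1:100) {
    fp <- simulate_fp_titration(kd = 3.1, seed = i)  # 2% of range Gaussian noise
    fit <- fit_fp_binding(fp$conc, fp$polarization)
    kds[i] <- fit$kd
    ci <- confint(fit)
    covered[i] <- ci["lower"] <= 3.1 && 3.1 <= ci["upper"]
  }
  expect_lt(abs(stats::median(kds) - 3.1) / 3.1, 0.10)
  expect_lt(abs(mean(kds) - 3.1) / 3.1, 0.05)      # bias well under 5%
  expect_gte(mean(covered), 0.90)
})

test_that("thermal melts recover the midpoint and reject transition-free traces", {
  m <- simulate_melt(tm = 75, dh = 300, noise_sd = 0)
  fit <- fit_two_state_thermal(m$temperature, m$signal)
  expect_equal(fit$midpoint, 75, tolerance = 0.1)
  expect_equal(fit$dh, 300, tolerance = 0.01)
  ## at Tm the two-state signal sits halfway between the baselines
  T_K <- 75 + 273.15
  bf <- fit$baseline_folded["intercept"] + fit$baseline_folded["slope"] * T_K
  bu <- fit$baseline_unfolded["intercept"] + fit$baseline_unfolded["slope"] * T_K
  sig_tm <- dimerlab:::thermal_model(T_K, T_K, fit$dh, fit$baseline_folded[1],
                                     fit$baseline_folded[2], fit$baseline_unfolded[1],
                                     fit$baseline_unfolded[2])
  expect_equal(unname(sig_tm), unname((bf + bu) / 2), tolerance = 1e-9)
  ## affine rescaling of the signal axis leaves the midpoint unchanged
  fit2 <- fit_two_state_thermal(m$temperature, 3.7 * m$signal + 120)
  expect_equal(fit2$midpoint, fit$midpoint, tolerance = 1e-6)
  ## a flat (unfolded-like) trace has no transition to report
  flat <- simulate_melt(folded = FALSE, noise_sd = 0)
  expect_error(fit_two_state_thermal(flat$temperature, flat$signal),
               class = "dimerlab_no_transition")
  flat_noisy <- simulate_melt(folded = FALSE, noise_sd = 0.3, seed = 4)
  expect_error(fit_two_state_thermal(flat_noisy$temperature, flat_noisy$signal),
               class = "dimerlab_no_transition")
})

test_that("urea denaturation recovers Cm = dG0/m and rejects baseline-only data", {
  u <- simulate_urea(dg0 = 25, m = 10, noise_sd = 0)
  fit <- fit_two_state_chemical(u$denaturant, u$signal)
  expect_equal(fit$midpoint, 2.5, tolerance = 0.01)
  expect_equal(fit$m_value, 10, tolerance = 0.01)
  ## at u = Cm the unfolded fraction is exactly one half
  expect_equal(dimerlab:::two_state_fraction_chemical(fit$midpoint, fit$dg0, fit$m_value),
               0.5, tolerance = 1e-6)
  expect_error(fit_two_state_chemical(u$denaturant[u$denaturant <= 1],
                                      u$signal[u$denaturant <= 1]),
               "at least 10")
  base <- simulate_urea(folded = FALSE, noise_sd = 0.1, seed = 2)
  expect_error(fit_two_state_chemical(base$denaturant, base$signal),
               class = "dimerlab_no_transition")
})

test_that("midpoint recovery stays tight under realistic noise", {
  tms <- vapply(1:25, function(i) {
    m <- simulate_melt(tm = 75, dh = 300, noise_sd = 0.3, seed = i)
    fit_two_state_thermal(m$temperature, m$signal)$midpoint
  }, numeric(1))
  expect_lt(abs(mean(tms) - 75), 0.5)
  expect_true(all(abs(tms - 75) < 0.5))
  cms <- vapply(1:25, function(i) {
    u <- simulate_urea(dg0 = 25, m = 10, noise_sd = 0.15, seed = i)
    fit_two_state_chemical(u$denaturant, u$signal)$midpoint
  }, numeric(1))
  expect_lt(abs(mean(cms) - 2.5), 0.05)
  expect_true(all(abs(cms - 2.5) < 0.05))
})
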
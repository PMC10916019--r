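KB <- 1.380649e-5 # nN nm / K

test_that("equipartition inversion is exact on a series with known variance", {
  # crafted series with exact variance kB*T/0.3 nm^2 at T = 298 K
  target_var <- KB * 298 / 0.3
  z <- rep(c(-1, 1), 600) * sqrt(target_var * 1199 / 1200)
  expect_equal(stats::var(z), target_var)
  res <- thermal_noise_spring_constant(z, 298, beta = 1)
  expect_equal(res$spring_constant_N_per_m, 0.3)
  expect_equal(res$n_samples, 1200L)
})

test_that("thermal estimator recovers the true spring constant within 5%", {
  z <- generate_thermal_trace(0.3, 298, 10000, 10, seed = 42)
  res <- thermal_noise_spring_constant(z, 298)
  expect_lt(abs(res$spring_constant_N_per_m - 0.3) / 0.3, 0.05)
})

test_that("thermal estimator is scale-consistent and beta-linear", {
  z <- generate_thermal_trace(0.3, 298, 5000, 2, seed = 9)$deflection_nm
  base <- thermal_noise_spring_constant(z, 298)
  scaled <- thermal_noise_spring_constant(3 * z, 298)
  expect_equal(scaled$positional_variance_nm2, 9 * base$positional_variance_nm2)
  expect_equal(scaled$spring_constant_N_per_m,
               base$spring_constant_N_per_m / 9)
  corrected <- thermal_noise_spring_constant(z, 298, beta = 0.817)
  expect_equal(corrected$spring_constant_N_per_m,
               0.817 * base$spring_constant_N_per_m)
})

test_that("degenerate thermal inputs are rejected", {
  expect_error(thermal_noise_spring_constant(rep(1, 2000), 298), "variance")
  expect_error(thermal_noise_spring_constant(rnorm(100), 298), "1000")
  expect_error(thermal_noise_spring_constant(rnorm(2000), -1), "positive")
})

test_that("force conversion applies F = V * S * K with mean baseline removal", {
  n <- 1000
  t <- (seq_len(n) - 1) / 100
  meta <- quick_meta("cal", duration_s = 10, sampling_rate_hz = 100)
  # constant 0.05 V at S = 20 nm/V, K = 0.3 nN/nm: 0.3 nN before baseline
  tr <- deflection_trace(
    tibble::tibble(time_s = t, deflection_V = rep(0.05, n)),
    meta, quick_calib()
  )
  raw <- deflection_to_force(tr, baseline = "none")
  expect_equal(raw$force_nN, rep(0.05 * 20 * 0.3, n))
  sub <- deflection_to_force(tr)
  expect_equal(sub$force_nN, rep(0, n))
  expect_true(attr(sub, "baseline_removed"))
  expect_false(attr(raw, "baseline_removed"))

  # zero in, zero out
  z <- deflection_trace(
    tibble::tibble(time_s = t, deflection_V = rep(0, n)), meta, quick_calib()
  )
  expect_equal(deflection_to_force(z)$force_nN, rep(0, n))
})

test_that("conversion is linear and leaves zero-mean sinusoids untouched", {
  n <- 2000
  t <- (seq_len(n) - 1) / 100
  meta <- quick_meta("lin", duration_s = 20, sampling_rate_hz = 100)
  v1 <- sin(2 * pi * 0.5 * t)
  v2 <- cos(2 * pi * 1.5 * t) + 0.2
  mk <- function(v) deflection_trace(
    tibble::tibble(time_s = t, deflection_V = v), meta, quick_calib()
  )
  f <- function(v) deflection_to_force(mk(v), baseline = "none")$force_nN
  expect_equal(f(2.5 * v1 + v2), 2.5 * f(v1) + f(v2))
  # amplitude a volts -> amplitude a*S*K nN, unchanged by mean removal
  sub <- deflection_to_force(mk(0.1 * v1))
  expect_equal(sub$force_nN, 0.1 * 20 * 0.3 * v1, tolerance = 1e-9)
})

test_that("linear detrend removes a drift that mean removal cannot", {
  n <- 5000
  t <- (seq_len(n) - 1) / 100
  drift <- 0.02 + 0.01 * t
  meta <- quick_meta("drift", duration_s = 50, sampling_rate_hz = 100)
  tr <- deflection_trace(
    tibble::tibble(time_s = t, deflection_V = drift),
    meta, quick_calib()
  )
  lin <- deflection_to_force(tr, baseline = "linear")
  expect_lt(max(abs(lin$force_nN)), 1e-9)
  # mean removal alone leaves the sloped part in place
  mn <- deflection_to_force(tr, baseline = "mean")
  expect_gt(max(abs(mn$force_nN)), 0.5)
})

test_that("generator plus conversion recovers the noise-free force signal", {
  prof <- phenotype_profile(
    "linear",
    beat_component(c(2, 8), c(0.5, 0.3), phase = c(0.4, 1.1), am_rate_hz = 0),
    baseline_offset_nN = -1.2, noise_sd_nN = 0, burst_duty = 1
  )
  meta <- quick_meta("rec", duration_s = 10, sampling_rate_hz = 500)
  tr <- generate_cell_trace(prof, meta, quick_calib(), seed = 1)
  got <- deflection_to_force(tr)$force_nN
  t <- tr$time_s
  truth <- 0.5 * sin(2 * pi * 2 * t + 0.4) + 0.3 * sin(2 * pi * 8 * t + 1.1)
  expect_lt(max(abs(got - (truth - mean(truth)))), 1e-9)
})
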
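test_that("a pure exact-bin tone lands in exactly one band", {
  tr <- tone_deflection(4, 1, phase = pi / 2) # cosine: grid hits the peak
  prof <- band_max_force(band_decompose(deflection_to_force(tr)))
  expect_equal(prof$max_force_nN[prof$band == "3-5 Hz"], 1, tolerance = 1e-9)
  expect_true(all(prof$max_force_nN[prof$band != "3-5 Hz"] < 1e-9))
  # the 3-5 Hz signal reproduces the input pointwise
  sig <- band_decompose(deflection_to_force(tr))
  expect_lt(max(abs(sig$`3-5 Hz` - sig$force_nN)), 1e-9)
})

test_that("superposed tones split into their bands with correct amplitudes", {
  two <- tone_deflection(c(1, 13), c(0.6, 0.2), phase = c(pi / 2, pi / 2))
  sig2 <- band_decompose(deflection_to_force(two))
  one_a <- band_decompose(deflection_to_force(tone_deflection(1, 0.6, pi / 2)))
  one_b <- band_decompose(deflection_to_force(tone_deflection(13, 0.2, pi / 2)))
  # superposition: decomposing the sum equals summing the decompositions
  expect_lt(max(abs(sig2$`0-2 Hz` - one_a$`0-2 Hz`)), 1e-9)
  expect_lt(max(abs(sig2$`12-14 Hz` - one_b$`12-14 Hz`)), 1e-9)
  prof <- band_max_force(sig2)
  expect_equal(prof$max_force_nN[prof$band == "0-2 Hz"], 0.6, tolerance = 1e-6)
  expect_equal(prof$max_force_nN[prof$band == "12-14 Hz"], 0.2,
               tolerance = 1e-6)
  expect_true(all(
    prof$max_force_nN[!prof$band %in% c("0-2 Hz", "12-14 Hz")] < 1e-9
  ))
})

test_that("a zero trace decomposes into zero band signals", {
  sig <- band_decompose(make_force(rep(0, 4000)))
  for (lab in attr(sig, "scheme")$label) {
    expect_equal(sig[[lab]], rep(0, 4000))
  }
})

test_that("band signals plus residual reconstruct the input", {
  set.seed(7)
  x <- rnorm(20000) # broadband, energy beyond the scheme
  sig <- band_decompose(make_force(x - mean(x)))
  scheme <- attr(sig, "scheme")
  recon <- rowSums(as.data.frame(sig)[, scheme$label]) + sig$residual_nN
  expect_lt(max(abs(recon - sig$force_nN)), 1e-8)
  # energy additivity: band power never exceeds total power
  band_power <- sum(sapply(scheme$label, function(l) sum(sig[[l]]^2)))
  expect_lte(band_power, sum(sig$force_nN^2) + 1e-9)
})

test_that("sign flip leaves band maxima unchanged", {
  tr <- generate_cell_trace(
    linear_profile(), quick_meta("sgn", duration_s = 20,
                                 sampling_rate_hz = 500),
    quick_calib(), seed = 5
  )
  f <- deflection_to_force(tr)
  neg <- make_force(-f$force_nN, 500, "sgn_neg")
  p1 <- band_max_force(band_decompose(f))
  p2 <- band_max_force(band_decompose(neg))
  expect_equal(p1$max_force_nN, p2$max_force_nN, tolerance = 1e-12)
})

test_that("circular time shifts move argmax times but not maxima", {
  tr <- generate_cell_trace(
    linear_profile(), quick_meta("shf", duration_s = 20,
                                 sampling_rate_hz = 500),
    quick_calib(), seed = 6
  )
  x <- deflection_to_force(tr)$force_nN
  shift <- 1234L
  xs <- c(x[(shift + 1):length(x)], x[1:shift])
  p1 <- band_max_force(band_decompose(make_force(x, 500)), guard_s = 0)
  p2 <- band_max_force(band_decompose(make_force(xs, 500)), guard_s = 0)
  expect_equal(p1$max_force_nN, p2$max_force_nN, tolerance = 1e-9)
  expect_false(all(p1$argmax_time_s == p2$argmax_time_s))
})

test_that("FFT masking equals direct convolution with the mask kernel", {
  # kernel built by explicit cosine sums, independent of the fft path
  fs <- 100
  n <- 1200
  set.seed(11)
  x <- rnorm(n)
  x <- x - mean(x)
  sig <- band_decompose(make_force(x, fs), make_band_scheme(0, 30, 3))
  scheme <- attr(sig, "scheme")
  for (i in c(1, 4, 10)) {
    bins <- which(
      (0:(n - 1)) * fs / n >= scheme$lo_hz[i] &
      (0:(n - 1)) * fs / n < scheme$hi_hz[i] &
      (0:(n - 1)) > 0 & (0:(n - 1)) < n / 2
    ) - 1L
    m <- 0:(n - 1)
    kern <- sapply(m, function(mm) 2 / n * sum(cos(2 * pi * bins * mm / n)))
    idx <- outer(0:(n - 1), 0:(n - 1), function(a, b) ((a - b) %% n) + 1L)
    y_direct <- as.numeric(matrix(kern[idx], n, n) %*% x)
    expect_lt(max(abs(y_direct - sig[[scheme$label[i]]])), 1e-9)
  }
})

test_that("an amplitude-modulated tone reports its envelope peak", {
  fs <- 1000
  dur <- 60
  t <- (0:(fs * dur - 1)) / fs
  env <- 0.8 * 0.5 * (1 - cos(2 * pi * 0.05 * t)) # peaks at 0.8, t = 10, 30, 50
  x <- env * sin(2 * pi * 4 * t)
  prof <- band_max_force(band_decompose(make_force(x, fs)))
  # oracle: grid maximum of the analytic signal inside the guarded window
  keep <- t >= 1 & t <= dur - 1
  oracle <- max(abs(x[keep]))
  expect_equal(prof$max_force_nN[prof$band == "3-5 Hz"], oracle,
               tolerance = 0.01)
  expect_equal(oracle, 0.8, tolerance = 0.01)
})

test_that("spectral preconditions are enforced", {
  f_raw <- make_force(rnorm(1000), 100, baseline_removed = FALSE)
  expect_error(band_decompose(f_raw), "[Bb]aseline")
  f <- make_force(rnorm(1000), 50)
  expect_error(band_decompose(f, make_band_scheme(0, 30, 3)), "Nyquist")
  sig <- band_decompose(make_force(rnorm(1000), 100))
  expect_error(band_max_force(sig, guard_s = 6), "guard")
})
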
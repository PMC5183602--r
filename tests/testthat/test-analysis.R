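test_that("population rate is counts over neurons times bin width", {
  raster <- tibble::tibble(population = "E", neuron = rep(1:50, 1),
                           time_ms = runif(50, 10, 11))
  r <- population_rate(raster, "E", n_neurons = 4000, window = c(0, 20))
  expect_equal(r$rate_hz[r$time_ms == 10], 50 / (4000 * 0.001))
  expect_equal(sum(r$rate_hz) * 4000 * 0.001, 50)   # conservation
  # linearity: doubling every spike doubles every bin
  r2 <- population_rate(dplyr::bind_rows(raster, raster), "E",
                        n_neurons = 4000, window = c(0, 20))
  expect_equal(r2$rate_hz, 2 * r$rate_hz)
  # empty raster gives zero rate everywhere
  r0 <- population_rate(raster[0, ], "E", n_neurons = 100, window = c(0, 5))
  expect_true(all(r0$rate_hz == 0))
  expect_error(population_rate(raster, "E", n_neurons = 0), "positive")
})

test_that("spectral peak recovers a planted sinusoid", {
  t <- seq(0, 999) / 1000
  r <- 20 + 10 * sin(2 * pi * 140 * t)
  pk <- oscillation_peak(r, bin_ms = 1)
  expect_equal(pk$frequency_hz, 140, tolerance = 1e-8)
  expect_equal(pk$amplitude, 10, tolerance = 0.01)
  expect_true(pk$oscillating)
  # offset invariance
  pk2 <- oscillation_peak(r + 35, bin_ms = 1)
  expect_equal(pk2$amplitude, pk$amplitude)
  # constant signal: no oscillation
  pk0 <- oscillation_peak(rep(12, 1000), bin_ms = 1)
  expect_false(pk0$oscillating)
  expect_error(oscillation_peak(r[1:5], bin_ms = 1), "short")
})

test_that("cross-correlation lag recovers planted delays with both methods", {
  t <- seq(0, 1999)
  a <- sin(2 * pi * 100 * t / 1000)
  b <- sin(2 * pi * 100 * (t - 2) / 1000)   # b delayed by 2 ms
  expect_equal(as.numeric(xcorr_lag(a, a, max_lag_ms = 5)), 0)
  l <- xcorr_lag(a, b, max_lag_ms = 5)
  expect_equal(as.numeric(l), 2, tolerance = 0.3)
  expect_equal(attr(l, "raw_lag_ms"), 2)
  # antisymmetry under argument swap
  expect_equal(as.numeric(xcorr_lag(b, a, max_lag_ms = 5)),
               -as.numeric(l), tolerance = 0.5)
  lf <- xcorr_lag(a, b, method = "fundamental", frequency_hz = 100)
  expect_equal(as.numeric(lf), 2, tolerance = 0.05)
  expect_error(xcorr_lag(a, rep(1, length(a))), "constant")
  expect_error(xcorr_lag(a, b, method = "fundamental"), "frequency")
})

test_that("phase shift is the frequency-lag product, linear in the lag", {
  expect_equal(phase_shift(140, 1), 50.4)
  expect_equal(phase_shift(200, -1.25), -90)
  expect_equal(phase_shift(140, 0), 0)
  a <- 0.7; b <- -1.3
  expect_equal(phase_shift(140, a + b),
               phase_shift(140, a) + phase_shift(140, b))
})

test_that("regime labels follow phase sign and frequency divergence", {
  d <- tibble::tibble(phi_deg = c(80, -60, 10),
                      f_e = c(150, 300, 150), f_i = c(150, 300, 300))
  out <- classify_regime(d)
  expect_equal(out$regime, c("EI_dominated", "II_dominated", "transition"))
})

test_that("pipeline recovers a planted phase from synthetic Poisson rasters", {
  spec <- synthetic_raster_spec(tibble::tibble(
    population = c("E", "I"), n = c(2000, 500), base_hz = c(20, 30),
    depth_hz = c(15, 20), f_hz = 100, lag_ms = c(0, 1.5)),
    duration_ms = 2000, seed = 42)
  out <- generate_synthetic_raster(spec)
  re <- population_rate(out$raster, "E", n_neurons = 2000,
                        window = c(0, 2000))
  ri <- population_rate(out$raster, "I", n_neurons = 500,
                        window = c(0, 2000))
  pk <- oscillation_peak(re)
  expect_true(pk$oscillating)
  expect_equal(pk$frequency_hz, 100, tolerance = 0.01)
  lag <- xcorr_lag(re, ri, max_lag_ms = 1000 / pk$frequency_hz / 2)
  phi <- phase_shift(pk$frequency_hz, lag)
  # within one bin-equivalent of phase (360 * f * bin)
  expect_lt(abs(phi - 54), 360 * 100 * 0.001)
})
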
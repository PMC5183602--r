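test_that("gating cascade derivative and impulse response are exact", {
  # zero state is a fixed point
  d0 <- gating_derivative(0, 0, tau_rise = 0.2, tau_decay = 5)
  expect_equal(d0$dx, 0)
  expect_equal(d0$ds, 0)
  # GABA kinetics: x = 1, S = 0 gives dS = 1, dx = -5
  d <- gating_derivative(1, 0, tau_rise = 0.2, tau_decay = 5)
  expect_equal(d$ds, 1)
  expect_equal(d$dx, -5)
  # unit-impulse response matches the bi-exponential closed form
  taus <- list(c(0.2, 2), c(0.2, 5), c(10, 100))
  for (tt in taus) {
    dt <- 0.002
    n <- round(8 * tt[2] / dt)
    x <- 1; s <- 0
    ts <- seq_len(n) * dt
    keep <- round(c(0.5, 1, 3, 6) * tt[2] / dt)
    got <- numeric(length(keep))
    for (i in seq_len(n)) {
      y <- rk2_step(function(y) {
        g <- gating_derivative(y[1], y[2], tt[1], tt[2])
        c(g$dx, g$ds)
      }, c(x, s), dt)
      x <- y[1]; s <- y[2]
      if (i %in% keep) got[match(i, keep)] <- s
    }
    expect_equal(got, gating_impulse_response(ts[keep], tt[1], tt[2]),
                 tolerance = 1e-5)
  }
})

test_that("spike impulses add exactly one per delta", {
  expect_equal(apply_spike_increments(0.3, 1L), 1.3)
  x <- c(0.1, 0.5, 2)
  expect_equal(apply_spike_increments(x, c(0L, 0L, 0L)), x)
  expect_equal(apply_spike_increments(0, 3L), 3)
  expect_error(apply_spike_increments(0, -1L), "negative")
})

test_that("NMDA Mg block follows the printed expression", {
  expect_equal(nmda_block_denominator(0, 1), 1 + 1 / 3.57)
  expect_equal(nmda_block_denominator(-123.4, 0), 1)
  v <- seq(-90, 40, by = 2)
  b <- nmda_block_denominator(v, 1)
  expect_true(all(diff(b) < 0))            # monotone decreasing in V
  expect_true(all(b >= 1))
  expect_lt(nmda_block_denominator(300, 1) - 1, 1e-8)
  # hyperpolarization suppresses NMDA current despite larger driving force
  i80 <- postsynaptic_current(-80, g_nmda = 0.01)$i_nmda
  i20 <- postsynaptic_current(-20, g_nmda = 0.01)$i_nmda
  expect_lt(abs(i80), abs(i20))
})

test_that("postsynaptic currents follow the driving-force convention", {
  kin <- receptor_kinetics()
  # zero driving force at the receptor reversal
  z <- postsynaptic_current(0, g_ampa = 0.5, g_nmda = 0.5)
  expect_equal(z$i_ampa, 0)
  expect_equal(z$i_nmda, 0)
  expect_equal(postsynaptic_current(-70, g_gaba = 1)$i_gaba, 0)
  # direct arithmetic: (-60 + 70) * 0.01 = 0.1 nA
  r <- postsynaptic_current(-60, g_gaba = 0.01)
  expect_equal(r$i_gaba, 0.1)
  expect_equal(r$i_total, r$i_ampa + r$i_nmda + r$i_gaba)
  expect_error(postsynaptic_current(-60, g_ampa = -1), "negative")
})

test_that("Poisson background has the right moments and is seed-deterministic", {
  expect_equal(poisson_background(0, 0.02, 100), rep(0L, 100))
  set.seed(42)
  k <- poisson_background(1, 0.02, 1e6)
  expect_lt(abs(mean(k) - 0.02), 3 * sqrt(0.02 / 1e6))
  expect_lt(abs(var(k) - 0.02), 4 * sqrt(2 * 0.02^2 / 1e6) + 0.001)
  set.seed(7); a <- poisson_background(1, 0.02, 1000)
  set.seed(7); b <- poisson_background(1, 0.02, 1000)
  set.seed(8); c <- poisson_background(1, 0.02, 1000)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(poisson_background(-1, 0.02, 10), "negative")
})

test_that("long-run mean of the driven cascade matches the linear prediction", {
  # impulses at rate r: mean x = r tau_r, mean S = r tau_r tau_d
  r <- 0.5                      # impulses per ms
  tau_r <- 0.2; tau_d <- 2
  dt <- 0.02
  period <- round(1 / r / dt)   # one impulse every 2 ms, deterministic
  x <- 0; s <- 0
  n <- round(400 / dt)
  svals <- numeric(n)
  for (i in seq_len(n)) {
    if (i %% period == 1) x <- x + 1
    y <- rk2_step(function(y) c(-y[1] / tau_r, -y[2] / tau_d + y[1]),
                  c(x, s), dt)
    x <- y[1]; s <- y[2]
    svals[i] <- s
  }
  tail_mean <- mean(svals[(n / 2):n])
  expect_equal(tail_mean, r * tau_r * tau_d, tolerance = 0.02)
  # synaptic state decays to nothing within 10 max(tau) of silence
  for (i in seq_len(round(10 * tau_d / dt))) {
    y <- rk2_step(function(y) c(-y[1] / tau_r, -y[2] / tau_d + y[1]),
                  c(x, s), dt)
    x <- y[1]; s <- y[2]
  }
  expect_lt(s, 1e-3)
  expect_lt(x, 1e-6)
})
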
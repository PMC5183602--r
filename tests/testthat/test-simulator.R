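test_that("one Heun step of pure decay matches the 2nd-order Taylor value", {
  # dx/dt = -x/tau, tau = 0.2 ms, dt = 0.02: 1 - 0.1 + 0.005
  got <- rk2_step(function(x) -x / 0.2, 1, 0.02)
  expect_equal(got, 0.905)
})

test_that("spike detection fires once per suprathreshold local maximum", {
  dt <- 0.5
  expect_length(detect_spikes(rep(-67, 100), dt), 0)
  tri <- c(seq(-67, 30, length.out = 21), seq(30, -67, length.out = 21)[-1])
  t1 <- detect_spikes(tri, dt)
  expect_equal(t1, 20 * dt)
  # two pulses, plateaus above threshold yield one event per maximum
  # (a flat top is reported once, at its trailing sample)
  v <- rep(-67, 40)
  v[10:12] <- c(20, 20, 20)
  v[25] <- 18
  expect_equal(detect_spikes(v, 1), c(11, 24))
  # sub-threshold maxima are ignored
  v2 <- rep(-67, 20); v2[8] <- 10
  expect_length(detect_spikes(v2, 1), 0)
})

test_that("C++ single-cell stepper agrees with an R reference integration", {
  p <- interneuron_params()
  dt <- 0.02
  tr <- integrate_neuron("interneuron", i_ext = 0.5, duration_ms = 5,
                         dt_ms = dt, v0 = -67, params = p)
  y <- c(v = -67,
         m = gate_steady_state("interneuron", "m", -67),
         h = gate_steady_state("interneuron", "h", -67),
         n = gate_steady_state("interneuron", "n", -67))
  f <- function(y) {
    d <- interneuron_derivative(as.list(y), i_syn = 0, i_ext = 0.5,
                                params = p)
    c(d$dv, d$dm, d$dh, d$dn)
  }
  for (i in seq_len(nrow(tr) - 1)) y <- rk2_step(f, y, dt)
  expect_equal(unname(y[1]), tr$v[nrow(tr)], tolerance = 1e-9)
  expect_equal(unname(y[4]), tr$n[nrow(tr)], tolerance = 1e-9)
})

test_that("integrator converges at second order on a single-neuron trajectory", {
  ref <- integrate_neuron("interneuron", i_ext = 0.05, duration_ms = 10,
                          dt_ms = 1e-4)
  err <- vapply(c(0.04, 0.02), function(dt) {
    tr <- integrate_neuron("interneuron", i_ext = 0.05, duration_ms = 10,
                           dt_ms = dt)
    idx <- seq(1, nrow(ref), by = round(dt / 1e-4))
    max(abs(tr$v - ref$v[idx]))
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("interneuron fires repetitively with a monotone f-I curve", {
  rate <- vapply(c(0.3, 0.6, 1.2, 2), function(i) {
    tr <- integrate_neuron("interneuron", i_ext = i, duration_ms = 500)
    length(detect_spikes(tr$v, 0.02)) * 2
  }, numeric(1))
  expect_true(all(rate > 5))              # repetitive firing throughout
  expect_true(all(diff(rate) > 0))        # monotone in injected current
})

test_that("degenerate simulations behave as fixed points", {
  cfg0 <- network_config("EI_only", n_e = 20, n_i = 10, g_ei = 0.01,
                         g_ie = 0.01, duration_ms = 0, warmup_ms = 0,
                         seed = 1)
  sim0 <- simulate_network(cfg0)
  expect_equal(nrow(sim0$raster), 0)
  # no recurrence, no background: after the decay of the randomized
  # initial conditions (a depolarized start inside the Na window can
  # crawl to a single spike on the 50-ms membrane time scale), the
  # network is subthreshold forever
  cfg <- network_config("EI_only", n_e = 40, n_i = 10, nu_e = 0, nu_i = 0,
                        duration_ms = 400, seed = 2)
  sim <- simulate_network(cfg)
  expect_equal(sum(sim$raster$time_ms > 200), 0)
  # started exactly at rest, it never fires at all
  tr <- integrate_neuron("interneuron", i_ext = 0, duration_ms = 200)
  expect_length(detect_spikes(tr$v, 0.02), 0)
})

test_that("simulations are deterministic and recording does not perturb them", {
  cfg <- network_config("EI_only", n_e = 100, n_i = 25, g_ei = 0.08,
                        g_ie = 0.12, nu_e = 15, nu_i = 1,
                        duration_ms = 200, warmup_ms = 50, seed = 9)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$traces, s2$traces)
  s3 <- simulate_network(cfg, recorder = recorder_spec(
    v_ids_e = 1:3, v_ids_i = 1:2, v_stride = 10))
  expect_identical(s1$raster, s3$raster)
  expect_false(is.null(s3$v_traces))
  expect_true(all(c("population", "neuron", "time_ms", "v") %in%
                    names(s3$v_traces)))
  cfg$seed <- 10L
  s4 <- simulate_network(cfg)
  expect_false(identical(s1$raster, s4$raster))
  # spike times strictly increasing per neuron, inside [0, duration]
  per <- dplyr::group_by(s1$raster, .data$population, .data$neuron)
  per <- dplyr::summarise(per, ok = all(diff(time_ms) > 0),
                          .groups = "drop")
  expect_true(all(per$ok))
  expect_true(all(s1$raster$time_ms >= 0 &
                    s1$raster$time_ms <= cfg$duration_ms))
  # traces carry every channel the lag decomposition needs
  expect_true(all(c("s_ampa", "s_gaba", "s_nmda", "g_ampa_on_e",
                    "g_gaba_on_e", "g_ampa_on_i", "g_gaba_on_i") %in%
                    names(s1$traces)))
})
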
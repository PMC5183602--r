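test_that("gating rates match their closed-form anchor values", {
  # removable singularity of alpha_m: limit is exactly 1 at V = -35
  expect_equal(gating_rates("interneuron", "m", -35)$alpha, 1)
  # beta_m exponent vanishes at V = -60
  expect_equal(gating_rates("interneuron", "m", -60)$beta, 4)
  # beta_h sigmoid midpoint at V = -28
  expect_equal(gating_rates("interneuron", "h", -28)$beta, 0.5)
  # pyramidal beta_n exponent vanishes at V = -44
  expect_equal(gating_rates("pyramidal", "n", -44)$beta, 0.125)
  # pyramidal alpha_m singularity at V = -33
  expect_equal(gating_rates("pyramidal", "m", -33)$alpha, 1)
})

test_that("alpha expressions are continuous through the singular voltage", {
  for (cell in c("interneuron", "pyramidal")) {
    v0 <- if (cell == "interneuron") -35 else -33
    near <- gating_rates(cell, "m", v0 + c(-1e-4, 1e-4))$alpha
    at <- gating_rates(cell, "m", v0)$alpha
    expect_lt(max(abs(near - at)), 1e-5)
  }
  expect_true(all(gating_rates("interneuron", "n",
                               seq(-100, 40, by = 0.5))$alpha >= 0))
})

test_that("rates are nonnegative and C++ transcription matches R", {
  v <- seq(-100, 50, by = 1.3)
  for (cell in c("interneuron", "pyramidal")) {
    kind <- if (cell == "interneuron") 0L else 1L
    for (gate in c("m", "h", "n")) {
      r <- gating_rates(cell, gate, v)
      expect_true(all(r$alpha >= 0) && all(r$beta >= 0))
      m <- eiphase:::cpp_gating_rates(kind, gate, v, FALSE)
      expect_equal(m[, 1], r$alpha, tolerance = 1e-12)
      expect_equal(m[, 2], r$beta, tolerance = 1e-12)
    }
  }
  # printed beta_n variant agrees between implementations too
  rp <- gating_rates("interneuron", "n", v, use_printed_beta_n = TRUE)
  mp <- eiphase:::cpp_gating_rates(0L, "n", v, TRUE)
  expect_equal(mp[, 2], rp$beta, tolerance = 1e-12)
})

test_that("interneuron membrane equation evaluates as written", {
  p <- interneuron_params()
  # all gates closed, V at leak reversal, 1 nA injected: dV/dt = 1 mV/ms
  d <- interneuron_derivative(list(v = -67, m = 0, h = 0, n = 0),
                              i_syn = 0, i_ext = 1, params = p)
  expect_equal(d$dv, 1)
  # leak equilibrium with spike conductances disabled is an exact rest
  p0 <- interneuron_params(g_na = 0, g_k = 0)
  st <- list(v = p0$e_l,
             m = gate_steady_state("interneuron", "m", p0$e_l),
             h = gate_steady_state("interneuron", "h", p0$e_l),
             n = gate_steady_state("interneuron", "n", p0$e_l))
  d0 <- interneuron_derivative(st, params = p0)
  expect_equal(d0$dv, 0)
  expect_equal(abs(d0$dm) + abs(d0$dh) + abs(d0$dn), 0, tolerance = 1e-12)
  # equal synaptic and external currents cancel
  st2 <- list(v = -50, m = 0.3, h = 0.5, n = 0.4)
  expect_equal(interneuron_derivative(st2, i_syn = 0.7, i_ext = 0.7)$dv,
               interneuron_derivative(st2)$dv)
  expect_error(interneuron_derivative(list(v = NaN, m = 0, h = 0, n = 0)),
               "non-finite")
})

test_that("pyramidal compartment equations evaluate as written", {
  p <- pyramidal_params()
  # coupling vanishes at equal potentials: matches uncoupled cell
  st <- list(v_s = -55, v_d = -55, m = 0.2, h = 0.6, n = 0.3, ca = 5)
  p_unc <- pyramidal_params(g_sd = 0, g_ds = 0)
  expect_equal(pyramidal_derivative(st, params = p)$dv_s,
               pyramidal_derivative(st, params = p_unc)$dv_s)
  expect_equal(pyramidal_derivative(st, params = p)$dv_d,
               pyramidal_derivative(st, params = p_unc)$dv_d)
  # Ca equation at V_d = 0, Ca = 0: influx only, from the printed I_Ca
  st0 <- list(v_s = -65, v_d = 0, m = 0, h = 0, n = 0, ca = 0)
  m_inf <- 1 / (1 + exp(-20 / 9))
  i_ca <- p$g_ca * m_inf^2 * (0 - p$e_ca)
  expect_equal(pyramidal_derivative(st0, params = p)$dca,
               -p$alpha_ca * i_ca)
  # AHP current vanishes at V_d = E_K regardless of Ca
  stk <- list(v_s = -65, v_d = -80, m = 0, h = 0, n = 0, ca = 30)
  stk0 <- modifyList(stk, list(ca = 0))
  expect_equal(pyramidal_derivative(stk, params = p)$dv_d,
               pyramidal_derivative(stk0, params = p)$dv_d)
  # synaptic current enters the soma only
  d_syn <- pyramidal_derivative(st, i_syn_soma = 1, params = p)
  d_nos <- pyramidal_derivative(st, params = p)
  expect_equal(d_syn$dv_d, d_nos$dv_d)
  expect_equal(d_syn$dv_s, d_nos$dv_s - 1 / p$c_m)
})

test_that("clamped-voltage relaxation reaches alpha/(alpha+beta)", {
  skip_if_not_installed("deSolve")
  for (cell in c("interneuron", "pyramidal")) {
    phi <- 1
    for (gate in c("m", "h", "n")) {
      v <- -50
      r <- gating_rates(cell, gate, v)
      sol <- deSolve::ode(
        y = c(x = 0.9), times = c(0, 400),
        func = function(t, y, parms)
          list(phi * (r$alpha * (1 - y) - r$beta * y)))
      expect_equal(unname(sol[2, "x"]), r$alpha / (r$alpha + r$beta),
                   tolerance = 1e-6)
    }
  }
})

test_that("passive membrane relaxes to E_L with the leak time constant", {
  # interneuron: C/g_L = 1/0.02 = 50 ms
  p <- interneuron_params(g_na = 0, g_k = 0)
  tr <- integrate_neuron("interneuron", duration_ms = 100, v0 = p$e_l + 10,
                         params = p)
  expect_equal(tr$v[tr$time_ms == 50], p$e_l + 10 * exp(-1),
               tolerance = 1e-5)
  expect_true(all(diff(tr$v) <= 0))     # monotone decay
  # pyramidal soma: C/g_L = 0.25/0.025 = 10 ms (all active currents off)
  pp <- pyramidal_params(g_na = 0, g_k = 0, g_ca = 0, g_ahp = 0,
                         g_sd = 0, g_ds = 0)
  trp <- integrate_neuron("pyramidal", duration_ms = 50, v0 = pp$e_l + 10,
                          params = pp)
  expect_equal(trp$v[trp$time_ms == 10], pp$e_l + 10 * exp(-1),
               tolerance = 1e-4)
})

test_that("gating variables stay in [0,1] and Ca stays nonnegative while spiking", {
  tr <- integrate_neuron("interneuron", i_ext = 1, duration_ms = 300)
  expect_true(all(tr$m >= 0 & tr$m <= 1))
  expect_true(all(tr$h >= 0 & tr$h <= 1))
  expect_true(all(tr$n >= 0 & tr$n <= 1))
  trp <- integrate_neuron("pyramidal", i_ext = 1.5, duration_ms = 300)
  expect_true(all(trp$ca >= 0))
  expect_true(all(trp$m >= 0 & trp$m <= 1))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(interneuron_params(c_m = 0))
  expect_error(interneuron_params(e_k = 0))     # needs E_K < E_L
  expect_error(pyramidal_params(p_soma = 1))
  expect_error(pyramidal_params(tau_ca = -1))
  expect_error(gating_rates("interneuron", "q", -50))
})
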
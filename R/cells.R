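#' Voltage-dependent gating rates
#'
#' Opening (`alpha`) and closing (`beta`) rates, in 1/ms, of the m, h and n
#' spike gates for either cell kind. The alpha expressions of the m and n
#' gates have a removable singularity (0/0) at one voltage; they are
#' evaluated by their analytic limit there.
#'
#' This is the plain-R reference implementation; the simulator uses an
#' identical C++ transcription, and the two are cross-checked in the tests.
#'
#' @param cell `"interneuron"` or `"pyramidal"`.
#' @param gate `"m"`, `"h"` or `"n"`.
#' @param v Membrane potential(s), mV.
#' @param use_printed_beta_n Sigmoid variant of the interneuron n-gate
#'   closing rate (see [interneuron_params()]).
#' @return A tibble with columns `v`, `alpha`, `beta`.
#' @export
#' @examples
#' gating_rates("interneuron", "m", -35)   # alpha exactly 1 at the limit
gating_rates <- function(cell = c("interneuron", "pyramidal"),
                         gate = c("m", "h", "n"), v,
                         use_printed_beta_n = FALSE) {
  cell <- match.arg(cell)
  gate <- match.arg(gate)
  stopifnot(is.numeric(v), all(is.finite(v)))
  trap <- function(a, u) {
    out <- ifelse(abs(u) < 1e-7, 10 * a, a * u / (1 - exp(-0.1 * u)))
    out
  }
  if (cell == "interneuron") {
    ab <- switch(gate,
      m = list(trap(0.1, v + 35), 4 * exp(-(v + 60) / 18)),
      h = list(0.07 * exp(-(v + 58) / 20), 1 / (1 + exp(-0.1 * (v + 28)))),
      n = list(trap(0.01, v + 34),
               if (use_printed_beta_n) 1 / (1 + exp(-0.1 * (v + 44) / 80))
               else 0.125 * exp(-(v + 44) / 80)))
  } else {
    ab <- switch(gate,
      m = list(trap(0.1, v + 33), 4 * exp(-(v + 58) / 12)),
      h = list(0.07 * exp(-0.1 * (v + 50)), 1 / (1 + exp(-0.1 * (v + 20)))),
      n = list(trap(0.01, v + 33), 0.125 * exp(-0.04 * (v + 44))))
  }
  tibble::tibble(v = v, alpha = ab[[1]] + 0 * v, beta = ab[[2]] + 0 * v)
}

#' Steady-state gate value at a clamped potential
#'
#' `x_inf = alpha / (alpha + beta)` for the requested gate.
#'
#' @inheritParams gating_rates
#' @return Numeric vector of steady-state values in \[0, 1\].
#' @export
gate_steady_state <- function(cell, gate, v, use_printed_beta_n = FALSE) {
  r <- gating_rates(cell, gate, v, use_printed_beta_n)
  r$alpha / (r$alpha + r$beta)
}

#' Time derivative of the interneuron state
#'
#' Right-hand side of the single-compartment interneuron membrane equation
#' `C_m dV/dt = -I_L - I_Na - I_K - I_syn + I_ext` together with the
#' first-order gate kinetics `dx/dt = phi_x (alpha_x (1 - x) - beta_x x)`.
#'
#' @param state Named list or vector with `v`, `m`, `h`, `n`.
#' @param i_syn Synaptic current (nA, positive = outward in the
#'   `-I_syn` convention).
#' @param i_ext External injected current (nA).
#' @param params [interneuron_params()].
#' @return Named list `dv`, `dm`, `dh`, `dn` (per ms).
#' @export
interneuron_derivative <- function(state, i_syn = 0, i_ext = 0,
                                   params = interneuron_params()) {
  s <- as.list(state)
  if (!all(is.finite(unlist(s[c("v", "m", "h", "n")]))))
    abort("non-finite interneuron state")
  v <- s$v
  rm_ <- gating_rates("interneuron", "m", v, params$use_printed_beta_n)
  rh <- gating_rates("interneuron", "h", v, params$use_printed_beta_n)
  rn <- gating_rates("interneuron", "n", v, params$use_printed_beta_n)
  i_na <- params$g_na * s$m^3 * s$h * (v - params$e_na)
  i_k  <- params$g_k * s$n^4 * (v - params$e_k)
  i_l  <- params$g_l * (v - params$e_l)
  list(
    dv = (-i_l - i_na - i_k - i_syn + i_ext) / params$c_m,
    dm = params$phi_m * (rm_$alpha * (1 - s$m) - rm_$beta * s$m),
    dh = params$phi_h * (rh$alpha * (1 - s$h) - rh$beta * s$h),
    dn = params$phi_n * (rn$alpha * (1 - s$n) - rn$beta * s$n))
}

#' Time derivative of the two-compartment pyramidal cell state
#'
#' Somatic equation with spike currents, electrotonic coupling and all
#' synaptic input; dendritic equation with leak, high-threshold Ca current
#' `I_Ca = g_Ca m_inf^2(V_d) (V_d - E_Ca)` (with
#' `m_inf = 1/(1 + exp(-(V_d + 20)/9))`), Ca-activated AHP current
#' `I_AHP = g_AHP (V_d - E_K) Ca/(Ca + k_ahp)` and coupling; calcium
#' kinetics `dCa/dt = -alpha_ca I_Ca - Ca/tau_ca`.
#'
#' @param state Named list or vector with `v_s`, `v_d`, `m`, `h`, `n`, `ca`.
#' @param i_syn_soma Synaptic current into the soma (nA).
#' @param i_ext External injected current into the soma (nA).
#' @param params [pyramidal_params()].
#' @return Named list `dv_s`, `dv_d`, `dm`, `dh`, `dn`, `dca` (per ms).
#' @export
pyramidal_derivative <- function(state, i_syn_soma = 0, i_ext = 0,
                                 params = pyramidal_params()) {
  s <- as.list(state)
  if (!all(is.finite(unlist(s[c("v_s", "v_d", "m", "h", "n", "ca")]))))
    abort("non-finite pyramidal state")
  rm_ <- gating_rates("pyramidal", "m", s$v_s)
  rh <- gating_rates("pyramidal", "h", s$v_s)
  rn <- gating_rates("pyramidal", "n", s$v_s)
  i_na <- params$g_na * s$m^3 * s$h * (s$v_s - params$e_na)
  i_k  <- params$g_k * s$n^4 * (s$v_s - params$e_k)
  i_ls <- params$g_l * (s$v_s - params$e_l)
  m_inf <- 1 / (1 + exp(-(s$v_d + 20) / 9))
  i_ca  <- params$g_ca * m_inf^2 * (s$v_d - params$e_ca)
  i_ahp <- params$g_ahp * (s$v_d - params$e_k) * s$ca / (s$ca + params$k_ahp)
  i_ld  <- params$g_l * (s$v_d - params$e_l)
  list(
    dv_s = (-i_ls - i_na - i_k -
              params$g_sd * (s$v_s - s$v_d) / params$p_soma -
              i_syn_soma + i_ext) / params$c_m,
    dv_d = (-i_ld - i_ca - i_ahp -
              params$g_ds * (s$v_d - s$v_s) / (1 - params$p_soma)) /
      params$c_m,
    dm = params$phi_m * (rm_$alpha * (1 - s$m) - rm_$beta * s$m),
    dh = params$phi_h * (rh$alpha * (1 - s$h) - rh$beta * s$h),
    dn = params$phi_n * (rn$alpha * (1 - s$n) - rn$beta * s$n),
    dca = -params$alpha_ca * i_ca - s$ca / params$tau_ca)
}

#' One Heun (second-order Runge-Kutta) step
#'
#' Generic predictor-corrector step used by the reference integrators:
#' `y' = y + dt/2 (f(y) + f(y + dt f(y)))`.
#'
#' @param f Function of a numeric state vector returning its derivative.
#' @param y Numeric state vector.
#' @param dt Step size (ms).
#' @return Updated state vector.
#' @export
rk2_step <- function(f, y, dt) {
  stopifnot(dt > 0, all(is.finite(y)))
  k1 <- f(y)
  k2 <- f(y + dt * k1)
  y + dt / 2 * (k1 + k2)
}

#' Single-neuron trajectory under constant injected current
#'
#' Integrates one isolated cell with the same C++ Heun stepper used by the
#' network simulator. Useful for convergence checks, f-I curves and
#' membrane-time-constant validation.
#'
#' @param cell `"interneuron"` or `"pyramidal"`.
#' @param i_ext Constant injected current (nA; somatic for pyramidal).
#' @param duration_ms,dt_ms Integration horizon and step (ms).
#' @param v0 Initial potential (mV); gates start at steady state for `v0`,
#'   calcium at 0.
#' @param params Cell parameter set; defaults to the published constants.
#' @return Tibble with `time_ms`, `v` (somatic for pyramidal) and the
#'   remaining state columns.
#' @export
integrate_neuron <- function(cell = c("interneuron", "pyramidal"),
                             i_ext = 0, duration_ms = 100, dt_ms = 0.02,
                             v0 = NULL, params = NULL) {
  cell <- match.arg(cell)
  stopifnot(duration_ms > 0, dt_ms > 0)
  if (cell == "interneuron") {
    params <- params %||% interneuron_params()
    v0 <- v0 %||% params$e_l
    tr <- cpp_integrate_interneuron(params, i_ext, duration_ms, dt_ms, v0)
    tibble::tibble(time_ms = seq(0, by = dt_ms, length.out = nrow(tr)),
                   v = tr[, 1], m = tr[, 2], h = tr[, 3], n = tr[, 4])
  } else {
    params <- params %||% pyramidal_params()
    v0 <- v0 %||% params$e_l
    tr <- cpp_integrate_pyramidal(params, i_ext, duration_ms, dt_ms, v0)
    tibble::tibble(time_ms = seq(0, by = dt_ms, length.out = nrow(tr)),
                   v = tr[, 1], v_d = tr[, 2], m = tr[, 3], h = tr[, 4],
                   n = tr[, 5], ca = tr[, 6])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
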
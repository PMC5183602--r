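#' Derivative of the synaptic gating cascade
#'
#' Between presynaptic spikes the gating pair follows the linear cascade
#' `dS/dt = -S/tau_d + x`, `dx/dt = -x/tau_r`; spike impulses are applied
#' separately by [apply_spike_increments()]. After an isolated unit impulse
#' into `x`, `S(t)` is the bi-exponential
#' `tau_d tau_r/(tau_d - tau_r) (exp(-t/tau_d) - exp(-t/tau_r))`.
#'
#' @param x Rise variable(s), >= 0.
#' @param s Gating variable(s), >= 0.
#' @param tau_rise,tau_decay Time constants (ms).
#' @return List with `dx` and `ds` (per ms).
#' @export
gating_derivative <- function(x, s, tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0, all(is.finite(x)),
            all(is.finite(s)))
  list(dx = -x / tau_rise, ds = -s / tau_decay + x)
}

#' Apply presynaptic spike impulses to the rise variables
#'
#' Each delta impulse adds exactly 1 to the presynaptic neuron's rise
#' variable; `counts` carries the number of spikes per presynaptic neuron
#' in the current step.
#'
#' @param x Rise variables (numeric vector).
#' @param counts Non-negative integer spike counts, same length as `x`.
#' @return Updated rise variables.
#' @export
apply_spike_increments <- function(x, counts) {
  stopifnot(length(x) == length(counts))
  if (any(counts < 0)) abort("negative spike counts")
  x + counts
}

#' NMDA Mg-block denominator
#'
#' Voltage-dependent magnesium block factor
#' `1 + [Mg] exp(-0.062 V) / 3.57`, a monotonically decreasing function of
#' `v` that tends to 1 with depolarization or when `mg_mm = 0`. NMDA
#' current is divided by this factor.
#'
#' @param v Postsynaptic potential (mV).
#' @param mg_mm Mg concentration (mM).
#' @return Block factor >= 1.
#' @export
nmda_block_denominator <- function(v, mg_mm = 1) {
  stopifnot(mg_mm >= 0)
  1 + mg_mm * exp(-0.062 * v) / 3.57
}

#' Postsynaptic receptor currents
#'
#' Assembles the per-receptor currents from the summed presynaptic
#' conductances: `I_A = (V - E_AMPA) * gS_A`,
#' `I_N = (V - E_AMPA) * gS_N / block(V)`,
#' `I_G = (V - E_GABA) * gS_G`. These enter the membrane equations with a
#' minus sign, so a positive GABA current at `V > E_GABA` is
#' hyperpolarizing.
#'
#' @param v_post Postsynaptic potential (mV).
#' @param g_ampa,g_nmda,g_gaba Summed `g * S` conductances (uS), >= 0.
#' @param kin [receptor_kinetics()].
#' @return One-row tibble with `i_ampa`, `i_nmda`, `i_gaba`, `i_total` (nA).
#' @export
#' @examples
#' postsynaptic_current(-60, g_gaba = 0.01)   # 0.1 nA GABA current
postsynaptic_current <- function(v_post, g_ampa = 0, g_nmda = 0, g_gaba = 0,
                                 kin = receptor_kinetics()) {
  if (any(c(g_ampa, g_nmda, g_gaba) < 0))
    abort("negative summed conductance")
  i_a <- (v_post - kin$e_ampa) * g_ampa
  i_n <- (v_post - kin$e_ampa) * g_nmda /
    nmda_block_denominator(v_post, kin$mg_mm)
  i_g <- (v_post - kin$e_gaba) * g_gaba
  tibble::tibble(i_ampa = i_a, i_nmda = i_n, i_gaba = i_g,
                 i_total = i_a + i_n + i_g)
}

#' Poisson background event counts for one step
#'
#' Independent Poisson counts with mean `rate_khz * dt_ms` per neuron,
#' drawn from the current R random stream. These events feed each neuron's
#' private background AMPA channel.
#'
#' @param rate_khz Poisson rate per neuron (kHz = events/ms).
#' @param dt_ms Step size (ms).
#' @param n_neurons Number of neurons.
#' @return Integer vector of event counts.
#' @export
poisson_background <- function(rate_khz, dt_ms, n_neurons) {
  if (rate_khz < 0) abort("negative background rate")
  stopifnot(dt_ms > 0, n_neurons >= 0)
  rpois(n_neurons, rate_khz * dt_ms)
}

#' Closed-form impulse response of the gating cascade
#'
#' `S(t)` after a unit impulse into `x` at `t = 0`, used as an analytic
#' oracle for the cascade dynamics.
#'
#' @param t Time since the impulse (ms).
#' @param tau_rise,tau_decay Time constants (ms), `tau_rise != tau_decay`.
#' @return `S(t)`.
#' @export
gating_impulse_response <- function(t, tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0, tau_rise != tau_decay)
  tau_decay * tau_rise / (tau_decay - tau_rise) *
    (exp(-t / tau_decay) - exp(-t / tau_rise))
}
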
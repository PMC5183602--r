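#' Membrane parameters of the fast-spiking interneuron
#'
#' Single-compartment Hodgkin-Huxley interneuron constants: capacitance in
#' nF, conductances in uS, reversal potentials in mV, and the dimensionless
#' temperature-like kinetic scale factors `phi_*` applied to the gating
#' equations. Defaults are the model's published constants
#' (`c_m` = 1 nF, `g_l` = 0.02, `g_na` = 14, `g_k` = 1.8 uS,
#' `e_l` = -67, `e_na` = 55, `e_k` = -80 mV, phi = 5).
#'
#' The printed n-gate closing rate of this model is a sigmoid that differs
#' structurally from the classic fast-spiking interneuron it derives from;
#' by default the canonical decaying exponential
#' `beta_n = 0.125 exp(-(V + 44)/80)` is used, and
#' `use_printed_beta_n = TRUE` switches to the sigmoid variant.
#'
#' The kinetic scale factors default to 1. With the published value
#' `phi = 5` and this conductance set, the h-gate inactivates faster than
#' the comparatively weak sodium current can depolarize the cell: spikes
#' peak near -10 mV (below the +15 mV detection threshold) and constant
#' suprathreshold current drives the cell into depolarization block after
#' a single spike, so no repetitive fast-spiking behaviour exists. At
#' `phi = 1` the cell fires repetitive full-height spikes with a monotone
#' f-I curve. Set `phi_m = phi_h = phi_n = 5` to recover the published
#' kinetics verbatim.
#'
#' @param c_m Membrane capacitance (nF).
#' @param g_l,g_na,g_k Leak, sodium and potassium conductances (uS).
#' @param e_l,e_na,e_k Reversal potentials (mV).
#' @param phi_m,phi_h,phi_n Kinetic scale factors (dimensionless, > 0).
#' @param use_printed_beta_n Use the sigmoid n-gate closing rate variant.
#' @return A named list of class `eiphase_interneuron_params`.
#' @export
#' @examples
#' interneuron_params()$g_na
interneuron_params <- function(c_m = 1, g_l = 0.02, g_na = 14, g_k = 1.8,
                               e_l = -67, e_na = 55, e_k = -80,
                               phi_m = 1, phi_h = 1, phi_n = 1,
                               use_printed_beta_n = FALSE) {
  p <- list(c_m = c_m, g_l = g_l, g_na = g_na, g_k = g_k, e_l = e_l,
            e_na = e_na, e_k = e_k, phi_m = phi_m, phi_h = phi_h,
            phi_n = phi_n, use_printed_beta_n = isTRUE(use_printed_beta_n))
  stopifnot(p$c_m > 0, p$g_l >= 0, p$g_na >= 0, p$g_k >= 0,
            p$e_k < p$e_l, p$e_l < p$e_na,
            p$phi_m > 0, p$phi_h > 0, p$phi_n > 0)
  structure(p, class = c("eiphase_interneuron_params", "list"))
}

#' Membrane parameters of the two-compartment pyramidal cell
#'
#' Soma carries the spike-generating Na/K currents and receives all synaptic
#' input; the dendrite carries the high-threshold Ca current and the
#' Ca-activated AHP (after-hyperpolarization) potassium current. The two
#' compartments are coupled electrotonically with conductances `g_sd`
#' (soma equation) and `g_ds` (dendrite equation), scaled by the somatic
#' area fraction `p_soma`. Intracellular calcium follows
#' `dCa/dt = -alpha_ca * I_Ca - Ca/tau_ca` with `I_Ca` in the model's nA
#' current unit, and gates the AHP current through
#' `Ca / (Ca + k_ahp)`. The influx coefficient is published as
#' 4 uM/(ms uA); expressed per nA (the model's current unit) this is
#' `alpha_ca = 0.004`, the default. Setting `alpha_ca = 4` (4 uM per
#' nA ms, a thousandfold stronger influx) saturates the AHP and caps
#' sustained firing below ~5 Hz at any drive.
#'
#' Defaults are the published constants (`c_m` = 0.25 nF, `g_na` = 11.25,
#' `g_k` = 4.5, `g_l` = 0.025, `g_ca` = 0.25, `g_ahp` = 1.25 uS,
#' `e_ca` = 120 mV, `alpha_ca` = 4, `tau_ca` = 80 ms, `k_ahp` = 30 uM).
#' The coupling constants and area fraction are not part of the published
#' set; symmetric moderate coupling (`g_sd = g_ds` = 0.25 uS,
#' `p_soma` = 0.5) is the default, and the spike-gate phi factors default
#' to 1.
#'
#' @param c_m Membrane capacitance per compartment (nF).
#' @param g_l,g_na,g_k,g_ca,g_ahp Conductances (uS).
#' @param e_l,e_na,e_k,e_ca Reversal potentials (mV).
#' @param g_sd,g_ds Soma-dendrite coupling conductances (uS).
#' @param p_soma Somatic area fraction, in (0, 1).
#' @param alpha_ca Ca influx coefficient (uM per nA ms); 0.004 equals the
#'   published 4 uM/(ms uA).
#' @param tau_ca Ca decay time constant (ms).
#' @param k_ahp AHP half-saturation Ca concentration (uM).
#' @param phi_m,phi_h,phi_n Kinetic scale factors for the spike gates.
#' @return A named list of class `eiphase_pyramidal_params`.
#' @export
pyramidal_params <- function(c_m = 0.25, g_l = 0.025, g_na = 11.25,
                             g_k = 4.5, g_ca = 0.25, g_ahp = 1.25,
                             e_l = -65, e_na = 55, e_k = -80, e_ca = 120,
                             g_sd = 0.25, g_ds = 0.25, p_soma = 0.5,
                             alpha_ca = 0.004, tau_ca = 80, k_ahp = 30,
                             phi_m = 1, phi_h = 1, phi_n = 1) {
  p <- list(c_m = c_m, g_l = g_l, g_na = g_na, g_k = g_k, g_ca = g_ca,
            g_ahp = g_ahp, e_l = e_l, e_na = e_na, e_k = e_k, e_ca = e_ca,
            g_sd = g_sd, g_ds = g_ds, p_soma = p_soma, alpha_ca = alpha_ca,
            tau_ca = tau_ca, k_ahp = k_ahp, phi_m = phi_m, phi_h = phi_h,
            phi_n = phi_n)
  stopifnot(p$c_m > 0, p$p_soma > 0, p$p_soma < 1, p$tau_ca > 0,
            p$k_ahp > 0,
            all(unlist(p[c("g_l", "g_na", "g_k", "g_ca", "g_ahp",
                           "g_sd", "g_ds")]) >= 0))
  structure(p, class = c("eiphase_pyramidal_params", "list"))
}

#' Receptor kinetic constants
#'
#' Rise/decay time constants (ms) of the synaptic gating cascade for each
#' receptor, receptor reversal potentials (mV) and the Mg concentration (mM)
#' entering the NMDA voltage block. Defaults are the published constants:
#' rise 0.2 (GABA), 0.2 (AMPA), 10 (NMDA) ms; decay 5, 2, 100 ms;
#' `e_ampa` = 0 mV (shared by AMPA and NMDA), `e_gaba` = -70 mV,
#' `mg_mm` = 1 mM.
#'
#' @param tau_a_r,tau_a_d AMPA rise/decay time constants (ms).
#' @param tau_g_r,tau_g_d GABA rise/decay time constants (ms).
#' @param tau_n_r,tau_n_d NMDA rise/decay time constants (ms).
#' @param e_ampa,e_gaba Reversal potentials (mV).
#' @param mg_mm Extracellular Mg concentration (mM).
#' @return A named list of class `eiphase_kinetics`.
#' @export
receptor_kinetics <- function(tau_a_r = 0.2, tau_a_d = 2,
                              tau_g_r = 0.2, tau_g_d = 5,
                              tau_n_r = 10, tau_n_d = 100,
                              e_ampa = 0, e_gaba = -70, mg_mm = 1) {
  k <- list(tau_a_r = tau_a_r, tau_a_d = tau_a_d, tau_g_r = tau_g_r,
            tau_g_d = tau_g_d, tau_n_r = tau_n_r, tau_n_d = tau_n_d,
            e_ampa = e_ampa, e_gaba = e_gaba, mg_mm = mg_mm)
  stopifnot(all(unlist(k[1:6]) > 0), k$mg_mm >= 0)
  structure(k, class = c("eiphase_kinetics", "list"))
}
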
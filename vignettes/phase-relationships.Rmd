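---
title: "Phase relationships between excitatory and inhibitory populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase relationships between excitatory and inhibitory populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the model addresses

In many cortical and hippocampal recordings the discharges of pyramidal
cells precede those of interneurons by a consistent fraction of the
oscillation cycle. Two circuit mechanisms can generate the underlying
rhythm: a feedback loop in which pyramidal cells excite interneurons and
are silenced by the returning inhibition (the E-I loop, PING-type), and
mutual inhibition among interneurons alone (the I-I loop, ING-type), which
entrains pyramidal cells without any excitatory feedback. `eiphase`
implements a conductance-based spiking model of both loops — singly and in
combination — plus the measurement pipeline that turns spike rasters into
phase shifts, so the dependence of the E-I phase relationship on drive and
coupling can be simulated and decomposed.

## Model

**Interneurons** are single-compartment Hodgkin-Huxley cells
(`C_m dV/dt = -I_L - I_Na - I_K - I_syn + I_ext`) with fast-spiking
kinetics; gates follow `dx/dt = phi_x (alpha_x(V)(1-x) - beta_x(V) x)`.
**Pyramidal cells** have a somatic compartment carrying the spike currents
and all synaptic input, electrotonically coupled (conductances `g_sd`,
`g_ds`, area fraction `p`) to a dendritic compartment carrying a
high-threshold calcium current `I_Ca = g_Ca m_inf^2(V_d)(V_d - E_Ca)` and
a calcium-activated after-hyperpolarization current
`I_AHP = g_AHP (V_d - E_K) Ca/(Ca + 30 uM)`, with
`dCa/dt = -alpha I_Ca - Ca/tau_Ca`.

**Synapses.** Each presynaptic neuron drives one rise/decay gating cascade
per receptor (`dx/dt = -x/tau_r + sum_k delta(t - t_k)`,
`dS/dt = -S/tau_d + x`); postsynaptic current is the summed `g S` times
the driving force, with the NMDA current divided by the magnesium block
factor `1 + [Mg] exp(-0.062 V)/3.57`. Because all synapses from one
neuron share kinetics, one `(x, S)` pair per presynaptic neuron delivered
through the adjacency structure is mathematically identical to
per-synapse state. NMDA receptors are used on E-to-E connections only,
and only in the persistent-oscillation scenario. Background drive is an
independent Poisson train per neuron onto a private AMPA channel (1 kHz
at 2.48 nS for pyramidal cells and 1.9 nS for interneurons by default;
scenario configurations raise the rates as their regime requires).
Transmission is delay-free: a spike detected at one step increments the
rise variables at the start of the next (a delay hook exists in the
integration loop design but is fixed at one step).

**Integration** uses Heun's second-order Runge-Kutta at `dt = 0.02` ms,
with spike and background impulses applied at step boundaries. Spikes are
peaks of the somatic potential above +15 mV. Cells start at a uniformly
random potential in `[E_L, E_L + 10]` mV (gates at steady state, Ca = 0)
so the network desynchronizes quickly; the first 100 ms of every analysis
window are discarded (200 ms in the persistent scenario, whose drive is
withdrawn at 150 ms). Calcium is clamped at zero if a step undershoots;
the count of clamps is reported in the result rather than silently
discarded.

## Two departures from the published constant set

Two of the printed single-cell constants do not yield functioning cells,
and the package's defaults depart from them deliberately; both remain
configurable, so the printed values can be restored verbatim.

* **Interneuron kinetic scale `phi`.** With the printed `phi = 5` and the
  printed conductances (g_Na = 14, g_K = 1.8 uS on 1 nF), the h-gate
  inactivates faster than the comparatively weak sodium current can
  depolarize the cell: the spike peaks near -10 mV — below the +15 mV
  detection threshold printed alongside it — and a constant
  suprathreshold current drives the cell into depolarization block after
  a single spike (verified at `dt` down to 0.001 ms, and for
  `phi >= 1.5`). Since no repetitive fast-spiking behaviour exists
  anywhere in that regime, the default is `phi = 1`, which yields full
  spikes (+40 mV) and a monotone f-I curve over 0.2-2 nA.
* **Calcium influx coefficient.** The printed unit is uM/(ms uA) with
  value 4; the model's natural current unit is nA, where the same
  coefficient is 0.004. Implementing "4 per nA" saturates calcium and
  caps pyramidal firing below ~5 Hz at any drive; the unit-faithful
  0.004 is the default.

A third printed anomaly, the interneuron n-gate closing rate written as a
sigmoid `1/(1 + exp(-0.1(V+44)/80))` (nearly constant at 0.5 over the
physiological range), is replaced by default with the canonical
fast-spiking form `0.125 exp(-(V+44)/80)`; `use_printed_beta_n = TRUE`
restores the sigmoid.

A consequence worth stating plainly: with `phi = 1` the interneuron's
recovery kinetics are five times slower than the published model
intended, so the shipped networks oscillate in the 20-110 Hz band rather
than at 120-300 Hz. The phase *identities* and trend *directions* the
package tests are dimensionless and carry over; the printed frequencies
do not.

## Measurement pipeline

Population rates are spike counts per 1-ms bin divided by population size
and bin width. The oscillation frequency and amplitude are the largest
mean-subtracted DFT magnitude in a 20-500 Hz search band (amplitude
normalized to the equivalent sinusoid, `2|X_k|/n`); a peak is accepted
when it exceeds 5x the median in-band magnitude. The r_e to r_i lag is
the maximum of the mean-subtracted cross-correlation within half a
period, refined by parabolic interpolation (the raw bin lag is kept
alongside), and the phase shift is `360 f lag`, reported in
`(-180, 180]` with positive values meaning pyramidal cells lead.

The cycle decomposition measures four lags at the network frequency:
`Phi_P,syn` (mean AMPA gating behind r_e), `Phi_I,cell` (r_i behind its
oscillatory excitatory drive — the recurrent AMPA conductance onto
interneurons, or the sign-inverted GABA conductance in I-I-only
networks), `Phi_I,syn` (mean GABA gating behind r_i) and `Phi_P,cell`
(r_e behind the sign-inverted GABA conductance onto pyramidal cells).
The sign inversion of inhibition contributes 180 degrees, closing the
cycle: `Phi_P,cell + Phi_P,syn + Phi_I,cell + Phi_I,syn + 180 = 360`.
In an E-I-only network the r_e to r_i shift equals
`Phi_P,syn + Phi_I,cell`, hence is below 180 degrees — pyramidal cells
always lead. In an I-I-driven network the total from r_i to r_e is
`180 + Phi_I,syn + Phi_P,cell`: between 180 and 360 degrees the
pyramidal cells effectively lead, beyond 360 they lag, and which side a
network falls on is set by the pyramidal response speed.

For these four lags the estimator is not the cross-correlation argmax but
the phase of the cross-correlation's component at the oscillation
frequency (the cross-spectrum phase at the nearest DFT bin, exposed as
`method = "fundamental"` of `xcorr_lag()`). The population rates are
pulse-like, and at 1-ms bins the refined argmax between two differently
shaped waveforms carries a shape-dependent bias of tens of degrees that
does not cancel around the cycle; fundamental phases compose
consistently, which is what a cycle identity requires. The residual
closure error (a few degrees) is dominated by the phase difference
between a population's mean gating variable and its adjacency-weighted
counterpart, plus stochastic background noise. `phase_report()` reports
the r_e-to-r_i phase both ways (`phi_deg` argmax, `phi_fund_deg`
fundamental); the leading flag uses the fundamental estimate, which
stays stable when one population's modulation is weak.

## Scenarios and the choice of their parameters

The recurrent conductances behind the published figures are not stated
anywhere, so every shipped scenario fixes its own documented values,
found once by coarse grid search over each scenario's qualitative regime
and frozen (`scratch` scripts in the development tree; the values live in
`scenario_library()`). Desk-scale runs shrink populations by an integer
factor and multiply per-connection conductances by the same factor,
preserving the mean synaptic drive per neuron. Shipped sizes: the
E-I-only and combined baselines use 800/200 (one fifth of the published
4000/1000, conductances x5), trend sweeps use 400/100 at 400-500 ms, and
the I-I-only network ships at both the published 1000 interneurons and a
200-cell variant. These sizes keep the full test suite and the
acceptance script within minutes on one core; the phase measurements at
800/200 and 400/100 agree to a few degrees.

The trend sweeps (`sweep_library()`) probe directions, medians over three
seeds: the E-I phase shift falls with interneuron drive and with the
E-to-I conductance, rises with pyramidal drive; the I-I synaptic lag
rises with external drive and falls with the mutual-inhibition
conductance; the combined network's phase falls through zero (E-I to I-I
dominance transition) as either the interneuron drive or the I-to-E
conductance grows. Two regime notes: the pyramidal-drive trend holds
when the interneurons are tonically co-driven (`nu_i = 8` in the shipped
base) — with silent interneurons the recruitment-time shortening
outweighs the cycle-time shortening and the direction inverts; and the
I-to-E sign change requires moderate pyramidal drive, because a strongly
driven pyramidal population fires in the disinhibition window and leads
even when deeply inhibited.

The persistent scenario closes the loop on the E-I-dominance claim
without external input: NMDA conductance on E-to-E connections
(tau_decay = 100 ms) keeps the pyramidal population active after the
Poisson drive stops at 150 ms, strong feedback inhibition
(`g_ie = 0.6 uS`) keeps the interneurons phase-locked to the E rhythm,
and the control with `g_nmda = 0` falls silent within ~50 ms of
withdrawal.

## What the synthetic fixtures do and do not show

`generate_synthetic_raster()` draws inhomogeneous-Poisson spikes from
sinusoidally modulated rates with a planted inter-population lag. It
validates the estimator chain (binning, spectral peak, cross-correlation
lag, phase conversion) against exact ground truth — recovery within one
bin-equivalent of phase at 100 Hz. It shares with real simulations
neither waveform asymmetry nor cross-frequency structure, so estimator
bias on pulse-like waveforms is probed separately through the cycle
identities, and nothing in the fixture validates the neuron or synapse
dynamics themselves.

## Numerical choices and limitations

Removable singularities in the alpha-rate expressions are evaluated by
their analytic limit within 1e-7 of the singular voltage. The Heun
stepper is fixed-step; halving `dt` quarters the single-neuron global
error, and spike times shift by less than a bin. Lag searches are
restricted to half a period, making every reported lag principal-valued;
decomposed lags are wrapped to [0, 360) and the r_e-to-r_i phase to
(-180, 180]. Degenerate inputs (constant rates, windows shorter than ten
putative cycles, missing recorder channels) raise errors naming the
offending piece rather than returning numbers.

Known limitations: no synaptic delays, no short-term plasticity or NMDA
saturation, no spatial structure in the connectivity, a single shared
frequency estimate per run, and oscillation frequencies below the
published band for the reason given above. The `phi = 5` printed regime
is available but produces no usable fast-spiking interneuron; anyone
reproducing the published frequencies will need conductances the paper
does not provide.
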
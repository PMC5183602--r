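#' Recorder specification
#'
#' Controls which traces a simulation keeps. Population-mean gating
#' variables and synaptic conductances are always recorded in 1-ms bins
#' (they are needed by the lag decomposition); voltage dumps are kept for
#' an explicit subset of neurons at a configurable stride.
#'
#' @param bin_ms Trace bin width (ms).
#' @param v_ids_e,v_ids_i Neuron ids (1-based) whose membrane potential to
#'   dump; empty by default.
#' @param v_stride Keep every `v_stride`-th integration step of the
#'   voltage dumps.
#' @return List of class `eiphase_recorder`.
#' @export
recorder_spec <- function(bin_ms = 1, v_ids_e = integer(),
                          v_ids_i = integer(), v_stride = 5L) {
  stopifnot(bin_ms > 0, v_stride >= 1)
  structure(list(bin_ms = bin_ms, v_ids_e = as.integer(v_ids_e),
                 v_ids_i = as.integer(v_ids_i),
                 v_stride = as.integer(v_stride)),
            class = c("eiphase_recorder", "list"))
}

#' Simulate a network
#'
#' Builds the connectivity, initializes every neuron at a random potential
#' in `[E_L, E_L + 10]` mV with gates at steady state, and advances the
#' coupled neuron-synapse system with the Heun (second-order Runge-Kutta)
#' stepper at `dt_ms`. Spikes are detected as local maxima of the membrane
#' potential above the threshold (somatic potential for pyramidal cells);
#' a spike's synaptic impulse takes effect at the start of the following
#' step. Background Poisson events are drawn per neuron per step and
#' delivered to a private AMPA channel; they stop at `t_off_ms` if set.
#' The whole run is deterministic given `config$seed`.
#'
#' @param config An [network_config()].
#' @param recorder A [recorder_spec()].
#' @param keep_connectivity Retain the connectivity object in the result.
#' @return Object of class `eiphase_sim` with elements `raster` (tibble:
#'   `population`, `neuron`, `time_ms`), `traces` (tibble: `time_ms` plus
#'   population-mean channels `s_ampa`, `s_gaba`, `s_nmda`,
#'   `g_ampa_on_e`, `g_nmda_on_e`, `g_gaba_on_e`, `g_ampa_on_i`,
#'   `g_gaba_on_i`, `v_soma_mean`, `v_int_mean`), optional `v_traces`,
#'   `config`, and `ca_clamps` (count of calcium non-negativity clamps).
#' @export
simulate_network <- function(config, recorder = recorder_spec(),
                             keep_connectivity = FALSE) {
  cfg <- validate_config(config)
  stopifnot(inherits(recorder, "eiphase_recorder"))
  set.seed(cfg$seed)
  conn <- build_connectivity(cfg, reseed = FALSE)
  if (cfg$duration_ms == 0) {
    return(structure(list(
      raster = tibble::tibble(population = character(), neuron = integer(),
                              time_ms = numeric()),
      traces = tibble::tibble(time_ms = numeric()),
      v_traces = NULL, config = cfg, connectivity = conn,
      ca_clamps = 0), class = c("eiphase_sim", "list")))
  }
  cconf <- list(
    n_e = cfg$n_e, n_i = cfg$n_i, dt_ms = cfg$dt_ms,
    duration_ms = cfg$duration_ms,
    g_ee = cfg$g_ee, g_ei = cfg$g_ei, g_ie = cfg$g_ie, g_ii = cfg$g_ii,
    g_nmda = cfg$g_nmda,
    g_bg_e_us = cfg$g_bg_e * 1e-3, g_bg_i_us = cfg$g_bg_i * 1e-3,
    nu_e = cfg$nu_e, nu_i = cfg$nu_i, t_off_ms = cfg$t_off_ms,
    nmda_enabled = cfg$nmda_enabled, mg_mm = cfg$kinetics$mg_mm,
    threshold_mv = cfg$threshold_mv,
    i_ext_e = cfg$i_ext_e, i_ext_i = cfg$i_ext_i)
  cconn <- list(
    ee_pre = conn$ee$pre - 1L, ee_post = conn$ee$post - 1L,
    ei_pre = conn$ei$pre - 1L, ei_post = conn$ei$post - 1L,
    ie_pre = conn$ie$pre - 1L, ie_post = conn$ie$post - 1L,
    ii_pre = conn$ii$pre - 1L, ii_post = conn$ii$post - 1L)
  crec <- list(bin_ms = recorder$bin_ms,
               v_ids_e = recorder$v_ids_e - 1L,
               v_ids_i = recorder$v_ids_i - 1L,
               v_stride = recorder$v_stride)
  res <- cpp_simulate(cconf, cconn, cfg$interneuron, cfg$pyramidal,
                      cfg$kinetics, crec)
  raster <- dplyr::bind_rows(
    tibble::tibble(population = "E", neuron = res$spike_e_id + 1L,
                   time_ms = res$spike_e_t),
    tibble::tibble(population = "I", neuron = res$spike_i_id + 1L,
                   time_ms = res$spike_i_t))
  raster <- dplyr::arrange(raster, .data$time_ms, .data$population,
                           .data$neuron)
  tr <- tibble::as_tibble(as.data.frame(res$traces))
  tr <- dplyr::mutate(tr,
    time_ms = (seq_len(nrow(tr)) - 1) * res$trace_bin_ms,
    .before = 1)
  v_traces <- NULL
  if (length(recorder$v_ids_e) || length(recorder$v_ids_i)) {
    tidy_dump <- function(mat, ids, pop) {
      if (length(ids) == 0 || nrow(mat) == 0) return(NULL)
      colnames(mat) <- as.character(ids)
      d <- tibble::as_tibble(as.data.frame(mat))
      d$time_ms <- (seq_len(nrow(d)) - 1) * recorder$v_stride * cfg$dt_ms
      d <- tidyr::pivot_longer(d, -"time_ms", names_to = "neuron",
                               values_to = "v")
      dplyr::mutate(d, population = pop,
                    neuron = as.integer(.data$neuron), .before = 1)
    }
    v_traces <- dplyr::bind_rows(
      tidy_dump(res$vdump_e, recorder$v_ids_e, "E"),
      tidy_dump(res$vdump_i, recorder$v_ids_i, "I"))
  }
  structure(list(raster = raster, traces = tr, v_traces = v_traces,
                 config = cfg,
                 connectivity = if (keep_connectivity) conn else NULL,
                 ca_clamps = res$ca_clamps),
            class = c("eiphase_sim", "list"))
}

#' @export
print.eiphase_sim <- function(x, ...) {
  cfg <- x$config
  ne_sp <- sum(x$raster$population == "E")
  ni_sp <- sum(x$raster$population == "I")
  cat(sprintf("<eiphase_sim> %s %d E / %d I, %g ms: %d E spikes, %d I spikes\n",
              cfg$topology, cfg$n_e, cfg$n_i, cfg$duration_ms, ne_sp, ni_sp))
  if (cfg$n_e > 0 && cfg$duration_ms > cfg$warmup_ms) {
    w <- cfg$duration_ms - cfg$warmup_ms
    cat(sprintf("  mean rate after warm-up: E %.1f Hz, I %.1f Hz\n",
                sum(x$raster$population == "E" &
                      x$raster$time_ms >= cfg$warmup_ms) /
                  cfg$n_e / w * 1000,
                sum(x$raster$population == "I" &
                      x$raster$time_ms >= cfg$warmup_ms) /
                  cfg$n_i / w * 1000))
  }
  invisible(x)
}

#' Detect spikes on a sampled voltage trace
#'
#' A spike is a local maximum of the trace whose value exceeds the
#' threshold; runs of samples above threshold yield one event per local
#' maximum. This mirrors the detection rule applied inside the simulator.
#'
#' @param v Uniformly sampled membrane potential (mV).
#' @param dt_ms Sampling step (ms).
#' @param threshold_mv Detection threshold (mV).
#' @return Numeric vector of spike times (ms, time of the peak sample).
#' @export
detect_spikes <- function(v, dt_ms, threshold_mv = 15) {
  stopifnot(is.numeric(v), dt_ms > 0)
  n <- length(v)
  if (n < 3) return(numeric())
  i <- 2:(n - 1)
  peak <- v[i] > threshold_mv & v[i] >= v[i - 1] & v[i] > v[i + 1]
  (i[peak] - 1) * dt_ms
}
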
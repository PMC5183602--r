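#' Raster plot of a simulation
#'
#' Spike raster with pyramidal cells (red) below and interneurons (blue)
#' above, the conventional view of these networks.
#'
#' @param object An `eiphase_sim`.
#' @param max_neurons Subsample cap per population for readability.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eiphase_sim <- function(object, max_neurons = 400, ...) {
  r <- object$raster
  keep_e <- min(object$config$n_e, max_neurons)
  keep_i <- min(object$config$n_i, max_neurons %/% 4)
  r <- dplyr::filter(r, (.data$population == "E" & .data$neuron <= keep_e) |
                       (.data$population == "I" & .data$neuron <= keep_i))
  r <- dplyr::mutate(r, y = ifelse(.data$population == "E", .data$neuron,
                                   keep_e + .data$neuron))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$time_ms, y = .data$y,
                                  colour = .data$population)) +
    ggplot2::geom_point(size = 0.3, shape = 16) +
    ggplot2::scale_colour_manual(values = c(E = "#c0392b", I = "#2c5f9e")) +
    ggplot2::labs(x = "time (ms)", y = "neuron",
                  title = object$config$label) +
    ggplot2::theme_minimal()
}

#' Population rates and synaptic gating over time
#'
#' Overlays the 1-ms population rates of both populations with the
#' population-mean AMPA and GABA gating variables (each trace scaled to
#' its own maximum), the view used to read lead/lag relations by eye.
#'
#' @param sim An `eiphase_sim`.
#' @param window Time window (ms), default the last 100 ms of the
#'   analysis window.
#' @return A ggplot object.
#' @export
plot_rates <- function(sim, window = NULL) {
  cfg <- sim$config
  window <- window %||% c(max(cfg$warmup_ms, cfg$duration_ms - 100),
                          cfg$duration_ms)
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  pieces <- list()
  if (cfg$n_e > 0) {
    re <- population_rate(sim, "E", window = window)
    pieces$r_e <- tibble::tibble(time_ms = re$time_ms,
                                 value = norm(re$rate_hz), signal = "r_e")
  }
  ri <- population_rate(sim, "I", window = window)
  pieces$r_i <- tibble::tibble(time_ms = ri$time_ms,
                               value = norm(ri$rate_hz), signal = "r_i")
  tr <- dplyr::filter(sim$traces, .data$time_ms >= window[1],
                      .data$time_ms < window[2])
  pieces$s_a <- tibble::tibble(time_ms = tr$time_ms,
                               value = norm(tr$s_ampa), signal = "S_A")
  pieces$s_g <- tibble::tibble(time_ms = tr$time_ms,
                               value = norm(tr$s_gaba), signal = "S_G")
  d <- dplyr::bind_rows(pieces)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                  colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "normalized amplitude",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phase shift across a sweep
#'
#' Median phase shift (and per-replicate points) against the swept
#' parameter, coloured by regime.
#'
#' @param object An `eiphase_sweep` from [run_sweep()].
#' @param response Column to plot, default `"phi_deg"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eiphase_sweep <- function(object, response = "phi_deg", ...) {
  d <- dplyr::filter(object, .data$status == "ok")
  med <- dplyr::summarise(dplyr::group_by(d, .data$value),
                          m = median(.data[[response]], na.rm = TRUE),
                          .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  y = .data[[response]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), alpha = 0.7) +
    ggplot2::geom_line(data = med, ggplot2::aes(y = .data$m)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = unique(d$parameter), y = response) +
    ggplot2::theme_minimal()
}
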
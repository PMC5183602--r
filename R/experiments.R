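#' Shipped scenario configurations
#'
#' Named, seeded configurations reproducing the qualitative oscillation
#' regimes of the model: a PING-type network driven by the E-I loop alone,
#' ING-type mutually inhibitory interneuron networks (with and without a
#' driven pyramidal population, in both the fast- and slow-pyramidal
#' response regimes), the combined-loop network, and the NMDA-sustained
#' persistent oscillation in which the external drive is withdrawn at
#' 150 ms.
#'
#' The recurrent conductances are not part of the published constant set;
#' the shipped values were fixed once by a coarse grid search over each
#' scenario's regime (oscillation in the 120-300 Hz band with the intended
#' lead/lag relation) and are documented here as the package's own
#' choices. `*_small` variants shrink the populations (with per-connection
#' conductances rescaled by [scale_scenario()]) for quick runs.
#'
#' @param seed Base seed stored in every configuration.
#' @return Named list of [network_config()] objects.
#' @export
scenario_library <- function(seed = 1L) {
  lib <- list()
  # E-I loop alone (PING): strongly driven pyramidal population recruits
  # the interneurons, whose feedback inhibition paces the cycle; scaled
  # from the full-size 4000/1000 network (factor 5 in size, x5 in
  # per-connection conductance)
  lib$ei_only_baseline <- network_config(
    "EI_only", n_e = 800, n_i = 200, g_ei = 0.02, g_ie = 0.03,
    nu_e = 15, nu_i = 1, duration_ms = 500, seed = seed,
    label = "ei_only_baseline")
  # mutually inhibitory interneurons (ING), full published size and a
  # 1/5-size variant
  lib$ii_only_1000 <- network_config(
    "II_only", n_e = 0, n_i = 1000, g_ii = 0.0004,
    nu_e = 0, nu_i = 17, duration_ms = 500, seed = seed,
    label = "ii_only_1000")
  lib$ii_only_200 <- scale_scenario(lib$ii_only_1000, 5)
  lib$ii_only_200$label <- "ii_only_200"
  # I-I loop driving a pyramidal population: fast pyramidal response
  # (strong drive to E, moderate inhibition) => E leads
  lib$ii_drives_e_fast <- network_config(
    "II_only", n_e = 400, n_i = 200, g_ii = 0.002, g_ie = 0.01,
    nu_e = 14, nu_i = 17, duration_ms = 500, seed = seed,
    label = "ii_drives_e_fast")
  # slow pyramidal response (strong inhibition, weak drive) => E lags
  lib$ii_drives_e_slow <- network_config(
    "II_only", n_e = 400, n_i = 200, g_ii = 0.002, g_ie = 0.06,
    nu_e = 10, nu_i = 17, duration_ms = 500, seed = seed,
    label = "ii_drives_e_slow")
  # combined loops, E-I dominated baseline
  lib$combined_baseline <- network_config(
    "combined", n_e = 800, n_i = 200, g_ee = 0.001, g_ei = 0.02,
    g_ie = 0.03, g_ii = 0.002, nu_e = 15, nu_i = 3.5,
    duration_ms = 500, seed = seed, label = "combined_baseline")
  # persistent oscillation: NMDA among pyramidal cells sustains the
  # rhythm after the Poisson drive is withdrawn at 150 ms; strong
  # feedback inhibition keeps the interneurons phase-locked
  lib$persistent_nmda <- network_config(
    "combined", n_e = 800, n_i = 200, g_ee = 0.001, g_ei = 0.10,
    g_ie = 0.60, g_ii = 0.008, g_nmda = 0.002, nmda_enabled = TRUE,
    nu_e = 15, nu_i = 3.5, t_off_ms = 150, duration_ms = 600,
    warmup_ms = 200, seed = seed, label = "persistent_nmda")
  # desk-size variants (half size, conductances x2)
  lib$ei_only_small <- scale_scenario(lib$ei_only_baseline, 2)
  lib$ei_only_small$label <- "ei_only_small"
  lib$combined_small <- scale_scenario(lib$combined_baseline, 2)
  lib$combined_small$label <- "combined_small"
  lib
}

#' Shipped parameter sweeps
#'
#' Sweep specifications reproducing the model's directional trends: in the
#' E-I-only network the phase shift falls with the interneuron drive and
#' with the E->I conductance and rises with the pyramidal drive; in the
#' I-I-only network the synaptic lag of S_G behind r_i rises with the
#' external drive and falls with the mutual-inhibition conductance; in the
#' combined network the phase shift falls, with a sign change (E-I to I-I
#' dominance transition), as either the interneuron drive or the I->E
#' conductance grows. Grids and bases were fixed together with the
#' scenario library.
#'
#' @param seed Base seed.
#' @param replicates Seeds per grid point.
#' @return Named list of [sweep_spec()] objects, each carrying a
#'   `response` attribute (the tidy column whose trend the sweep probes)
#'   and an `expected_sign` attribute (+1 or -1).
#' @export
sweep_library <- function(seed = 1L, replicates = 3) {
  lib <- scenario_library(seed)
  ei_a <- lib$ei_only_small                      # 400/100 PING base
  ei_b <- network_config("EI_only", n_e = 400, n_i = 100, g_ei = 0.02,
                         g_ie = 0.06, nu_e = 15, nu_i = 8,
                         duration_ms = 400, seed = seed,
                         label = "ei_nu_e_base")
  ii <- lib$ii_only_200
  ii$duration_ms <- 400
  comb <- lib$combined_small
  comb$duration_ms <- 400
  comb_gie <- network_config("combined", n_e = 400, n_i = 100,
                             g_ee = 0.002, g_ei = 0.04, g_ie = 0.012,
                             g_ii = 0.004, nu_e = 10, nu_i = 17,
                             duration_ms = 500, seed = seed,
                             label = "combined_gie_base")
  ei_a$duration_ms <- 400
  tag <- function(spec, response, sign) {
    attr(spec, "response") <- response
    attr(spec, "expected_sign") <- sign
    spec
  }
  list(
    ei_sweep_nu_i = tag(sweep_spec(ei_a, "nu_i", c(1, 3, 5, 7),
                                   replicates), "phi_fund_deg", -1),
    ei_sweep_nu_e = tag(sweep_spec(ei_b, "nu_e", c(10, 13, 16, 19),
                                   replicates), "phi_fund_deg", +1),
    ei_sweep_g_ei = tag(sweep_spec(ei_a, "g_ei", c(0.02, 0.04, 0.08, 0.16),
                                   replicates), "phi_fund_deg", -1),
    ii_sweep_nu_i = tag(sweep_spec(ii, "nu_i", c(9, 13, 17),
                                   replicates), "phi_i_syn", +1),
    ii_sweep_g_ii = tag(sweep_spec(ii, "g_ii", c(0.002, 0.005, 0.012, 0.03),
                                   replicates), "phi_i_syn", -1),
    combined_sweep_nu_i = tag(sweep_spec(comb, "nu_i", c(3.5, 8, 12.5, 17),
                                         replicates), "phi_fund_deg", -1),
    combined_sweep_g_ie = tag(sweep_spec(comb_gie, "g_ie",
                                         c(0.012, 0.02, 0.03, 0.045),
                                         replicates), "phi_fund_deg", -1))
}

#' Fetch one shipped scenario by name
#'
#' @param name Scenario name (see [scenario_library()]).
#' @param seed Base seed.
#' @return A [network_config()].
#' @export
scenario <- function(name, seed = 1L) {
  lib <- scenario_library(seed)
  if (!name %in% names(lib))
    abort(paste0("unknown scenario '", name, "'; available: ",
                 paste(names(lib), collapse = ", ")))
  lib[[name]]
}

#' Sweep specification
#'
#' @param base A [network_config()] used as the template.
#' @param key Name of the configuration entry to sweep (e.g. `"nu_i"`,
#'   `"g_ie"`).
#' @param values Monotone numeric grid.
#' @param replicates Seeds per grid point (>= 1).
#' @param seed_base First seed; replicate `r` at any grid point uses
#'   `seed_base + r - 1`.
#' @return List of class `eiphase_sweep_spec`.
#' @export
sweep_spec <- function(base, key, values, replicates = 3,
                       seed_base = base$seed) {
  stopifnot(inherits(base, "eiphase_config") || is.list(base),
            key %in% names(base), is.numeric(values),
            length(values) >= 1, replicates >= 1)
  if (length(values) > 1 && !all(diff(values) > 0) &&
      !all(diff(values) < 0))
    abort("sweep grid must be monotone")
  structure(list(base = base, key = key, values = values,
                 replicates = as.integer(replicates),
                 seed_base = as.integer(seed_base)),
            class = c("eiphase_sweep_spec", "list"))
}

#' Run a parameter sweep
#'
#' Simulates and analyses every grid point and replicate of the
#' specification, returning a tidy table (one row per run) with the swept
#' value, seed, the phase-report columns and the regime label. A failed
#' point is recorded with `status = "error"` and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param decompose Also compute the four-lag decomposition per run.
#' @return Tibble of class `eiphase_sweep`.
#' @export
run_sweep <- function(spec, decompose = FALSE) {
  stopifnot(inherits(spec, "eiphase_sweep_spec"))
  grid <- tidyr::expand_grid(value = spec$values,
                             replicate = seq_len(spec$replicates))
  rows <- purrr::pmap(grid, function(value, replicate) {
    cfg <- spec$base
    cfg[[spec$key]] <- value
    cfg$seed <- spec$seed_base + replicate - 1L
    res <- tryCatch({
      sim <- simulate_network(validate_config(cfg))
      rep <- phase_report(sim, decompose = decompose)
      dplyr::mutate(tidy(rep), status = "ok")
    }, error = function(e) {
      tibble::tibble(status = paste0("error: ", conditionMessage(e)))
    })
    dplyr::mutate(res, parameter = spec$key, value = value,
                  seed = spec$seed_base + replicate - 1L, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (all(c("phi_deg", "f_e", "f_i") %in% names(out)))
    out <- classify_regime(out)
  class(out) <- c("eiphase_sweep", class(out))
  out
}

#' Median trend across a sweep
#'
#' Per-grid-point medians over replicates plus the Spearman rank
#' correlation between the swept value and the median of `response`
#' (its sign is the trend direction).
#'
#' @param sweep Result of [run_sweep()].
#' @param response Column to summarize (default `"phi_deg"`).
#' @return List with `medians` (tibble) and `spearman_rho`.
#' @export
sweep_trend <- function(sweep, response = "phi_deg") {
  stopifnot(is.data.frame(sweep), response %in% names(sweep))
  med <- dplyr::summarise(
    dplyr::group_by(sweep, .data$value),
    median_response = median(.data[[response]], na.rm = TRUE),
    .groups = "drop")
  rho <- suppressWarnings(
    stats::cor(med$value, med$median_response, method = "spearman",
               use = "complete.obs"))
  list(medians = med, spearman_rho = rho)
}

#' Synthetic raster specification
#'
#' Populations of inhomogeneous Poisson neurons with sinusoidally
#' modulated rates, used to test the measurement pipeline against planted
#' ground truth. Each population row defines a base rate (Hz), modulation
#' amplitude (Hz), shared frequency (Hz) and a planted lag (ms) of the
#' rate profile.
#'
#' @param populations Tibble with columns `population`, `n`, `base_hz`,
#'   `depth_hz`, `f_hz`, `lag_ms`.
#' @param duration_ms Duration (ms).
#' @param seed Seed.
#' @return List of class `eiphase_raster_spec`.
#' @export
synthetic_raster_spec <- function(populations, duration_ms = 2000,
                                  seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("population", "n", "base_hz", "depth_hz", "f_hz",
                  "lag_ms") %in% names(populations)))
  if (any(populations$depth_hz > populations$base_hz))
    abort("modulation depth exceeds base rate: negative instantaneous rate")
  structure(list(populations = tibble::as_tibble(populations),
                 duration_ms = duration_ms, seed = as.integer(seed)),
            class = c("eiphase_raster_spec", "list"))
}

#' Generate a synthetic oscillatory raster
#'
#' Draws inhomogeneous-Poisson spikes from the sinusoidal rate profiles of
#' the specification (thinning on a 0.1-ms grid) and returns both the
#' raster and the planted inter-population lags.
#'
#' @param spec A [synthetic_raster_spec()].
#' @return List with `raster` (tibble `population`, `neuron`, `time_ms`)
#'   and `truth` (the population table of the spec).
#' @export
generate_synthetic_raster <- function(spec) {
  stopifnot(inherits(spec, "eiphase_raster_spec"))
  set.seed(spec$seed)
  dt <- 0.1
  times <- seq(0, spec$duration_ms - dt, by = dt)
  rows <- purrr::pmap(spec$populations,
                      function(population, n, base_hz, depth_hz, f_hz,
                               lag_ms) {
    rate <- base_hz + depth_hz *
      sin(2 * pi * f_hz * (times - lag_ms) / 1000)
    lam <- n * rate * dt / 1000
    counts <- rpois(length(lam), lam)
    idx <- rep.int(seq_along(counts), counts)
    if (!length(idx))
      return(tibble::tibble(population = character(), neuron = integer(),
                            time_ms = numeric()))
    tibble::tibble(population = population,
                   neuron = sample.int(n, length(idx), replace = TRUE),
                   time_ms = times[idx] + runif(length(idx), 0, dt))
  })
  raster <- dplyr::arrange(dplyr::bind_rows(rows), .data$time_ms)
  list(raster = raster, truth = spec$populations)
}
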
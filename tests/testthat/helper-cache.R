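# simulations shared across test files (built once per test run)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# the E-I-only 800/200 conductance grid shared by several acceptance checks
ei_grid_values <- c(0.01, 0.015, 0.02, 0.03, 0.04)

ei_grid_reports <- function() {
  cached("ei_grid_reports", {
    purrr::map_dfr(ei_grid_values, function(g) {
      cfg <- scenario("ei_only_baseline")
      cfg$g_ei <- g
      sim <- simulate_network(validate_config(cfg))
      dplyr::mutate(tidy(phase_report(sim)), g_ei = g, .before = 1)
    })
  })
}

ii_report <- function() {
  cached("ii_report", {
    tidy(phase_report(simulate_network(scenario("ii_only_200"))))
  })
}
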
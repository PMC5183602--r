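test_that("scenario library ships every named configuration, validated", {
  lib <- scenario_library(seed = 3)
  expect_true(all(c("ei_only_baseline", "ii_only_1000", "ii_only_200",
                    "ii_drives_e_fast", "ii_drives_e_slow",
                    "combined_baseline", "persistent_nmda",
                    "ei_only_small", "combined_small") %in% names(lib)))
  for (cfg in lib) expect_s3_class(validate_config(cfg), "eiphase_config")
  # the 1/5-size variant compensates conductance by the same factor
  expect_equal(lib$ii_only_200$n_i, lib$ii_only_1000$n_i / 5)
  expect_equal(lib$ii_only_200$g_ii, lib$ii_only_1000$g_ii * 5)
  expect_equal(lib$persistent_nmda$t_off_ms, 150)
  expect_true(lib$persistent_nmda$nmda_enabled)
  expect_error(scenario("no_such_scenario"), "unknown")
  sw <- sweep_library(seed = 3, replicates = 2)
  expect_length(sw, 7)
  for (s in sw) {
    expect_s3_class(s, "eiphase_sweep_spec")
    expect_true(attr(s, "expected_sign") %in% c(-1, 1))
  }
})

test_that("run_sweep returns one tidy row per grid point and replicate", {
  base <- network_config("EI_only", n_e = 100, n_i = 25, g_ei = 0.08,
                         g_ie = 0.12, nu_e = 15, nu_i = 1,
                         duration_ms = 200, warmup_ms = 50, seed = 4)
  sw <- run_sweep(sweep_spec(base, "nu_e", 15, replicates = 3))
  expect_equal(nrow(sw), 3)
  expect_equal(sw$parameter, rep("nu_e", 3))
  expect_equal(sw$seed, 4:6)
  expect_true(all(c("phi_deg", "f_e", "f_i", "regime", "status") %in%
                    names(sw)))
  expect_error(sweep_spec(base, "nu_e", c(1, 3, 2)), "monotone")
  expect_error(sweep_spec(base, "not_a_key", 1))
  # failed points are recorded, not fatal
  bad <- base
  bad$duration_ms <- 30        # too short for spectral analysis
  bad$warmup_ms <- 0
  swb <- run_sweep(sweep_spec(bad, "nu_e", c(1, 15), replicates = 1))
  expect_equal(nrow(swb), 2)
  expect_true(all(grepl("error", swb$status) | swb$status == "ok"))
})

test_that("synthetic raster generator honours its specification", {
  pops <- tibble::tibble(population = "E", n = 500, base_hz = 30,
                         depth_hz = 0, f_hz = 120, lag_ms = 0)
  out <- generate_synthetic_raster(
    synthetic_raster_spec(pops, duration_ms = 1000, seed = 5))
  r <- population_rate(out$raster, "E", n_neurons = 500,
                       window = c(0, 1000))
  # unmodulated rates produce no spectral peak above the floor
  expect_false(oscillation_peak(r)$oscillating)
  expect_equal(mean(r$rate_hz), 30, tolerance = 0.1 * 30)
  # rates must stay nonnegative
  expect_error(synthetic_raster_spec(
    dplyr::mutate(pops, depth_hz = 40)), "negative")
  # deterministic given the seed
  o1 <- generate_synthetic_raster(
    synthetic_raster_spec(pops, duration_ms = 300, seed = 6))
  o2 <- generate_synthetic_raster(
    synthetic_raster_spec(pops, duration_ms = 300, seed = 6))
  expect_identical(o1$raster, o2$raster)
})

test_that("sweep trend summary reports per-point medians and a direction", {
  d <- tibble::tibble(value = rep(c(1, 2, 3), each = 3),
                      phi_deg = c(10, 11, 12, 7, 8, 9, 1, 2, 3))
  tr <- sweep_trend(d)
  expect_equal(tr$medians$median_response, c(11, 8, 2))
  expect_equal(tr$spearman_rho, -1)
})
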
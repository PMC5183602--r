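#' Network configuration
#'
#' Full description of one simulation: topology, population sizes,
#' connection probability, per-connection synaptic conductances (uS),
#' background Poisson rates (kHz) and conductances (nS), duration and
#' integration step (ms), and the seed. The topology constrains which
#' projections may exist: `EI_only` has only E->I and I->E, `II_only`
#' has I->I and I->E (no excitatory feedback), `combined` allows all
#' four.
#'
#' Conductance keys follow the projection naming `g_<post><pre>` used in
#' the field: `g_ei` is the E->I conductance seen by interneurons, `g_ie`
#' the I->E conductance seen by pyramidal cells, `g_ee` and `g_ii` the
#' within-population ones. `g_nmda` applies to E->E connections only and
#' is active when `nmda_enabled = TRUE`.
#'
#' @param topology `"combined"`, `"EI_only"` or `"II_only"`.
#' @param n_e,n_i Population sizes (`n_e` may be 0 for `II_only`).
#' @param p_conn Connection probability of each ordered pair.
#' @param g_ee,g_ei,g_ie,g_ii Per-connection AMPA/GABA conductances (uS).
#' @param g_nmda Per-connection E->E NMDA conductance (uS).
#' @param nmda_enabled Whether NMDA receptors are simulated.
#' @param nu_e,nu_i Background Poisson rates (kHz); defaults are 1.4/1 kHz
#'   for the combined topology and 1/1 kHz otherwise.
#' @param g_bg_e,g_bg_i Background AMPA conductances (nS; defaults 2.48
#'   and 1.9).
#' @param i_ext_e,i_ext_i Constant injected currents (nA), default 0.
#' @param duration_ms,dt_ms Simulated time and integration step (ms).
#' @param warmup_ms Initial transient discarded by all measurements (ms).
#' @param t_off_ms Time at which background input is withdrawn (`Inf` to
#'   keep it on).
#' @param seed Integer seed controlling connectivity, initial conditions
#'   and background noise.
#' @param use_printed_beta_n See [interneuron_params()].
#' @param interneuron,pyramidal,kinetics Parameter sets.
#' @param threshold_mv Spike detection threshold (mV).
#' @param label Optional scenario label.
#' @return A validated list of class `eiphase_config`.
#' @export
network_config <- function(topology = c("combined", "EI_only", "II_only"),
                           n_e = 4000, n_i = 1000, p_conn = 0.1,
                           g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0,
                           g_nmda = 0, nmda_enabled = FALSE,
                           nu_e = NULL, nu_i = NULL,
                           g_bg_e = 2.48, g_bg_i = 1.9,
                           i_ext_e = 0, i_ext_i = 0,
                           duration_ms = 500, dt_ms = 0.02,
                           warmup_ms = 100, t_off_ms = Inf, seed = 1L,
                           use_printed_beta_n = FALSE,
                           interneuron = interneuron_params(
                             use_printed_beta_n = use_printed_beta_n),
                           pyramidal = pyramidal_params(),
                           kinetics = receptor_kinetics(),
                           threshold_mv = 15, label = NULL) {
  topology <- match.arg(topology)
  nu_e <- nu_e %||% if (topology == "combined") 1.4 else 1
  nu_i <- nu_i %||% 1
  cfg <- list(topology = topology, n_e = as.integer(n_e),
              n_i = as.integer(n_i), p_conn = p_conn,
              g_ee = g_ee, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
              g_nmda = g_nmda, nmda_enabled = isTRUE(nmda_enabled),
              nu_e = nu_e, nu_i = nu_i, g_bg_e = g_bg_e, g_bg_i = g_bg_i,
              i_ext_e = i_ext_e, i_ext_i = i_ext_i,
              duration_ms = duration_ms, dt_ms = dt_ms,
              warmup_ms = warmup_ms, t_off_ms = t_off_ms,
              seed = as.integer(seed),
              interneuron = interneuron, pyramidal = pyramidal,
              kinetics = kinetics, threshold_mv = threshold_mv,
              label = label)
  class(cfg) <- c("eiphase_config", "list")
  validate_config(cfg)
}

#' Validate and normalize a network configuration
#'
#' Checks ranges and topology rules and returns the fully resolved
#' configuration. Topology rules: `EI_only` forbids `g_ee` and `g_ii`;
#' `II_only` forbids `g_ee` and `g_ei`; NMDA requires `nmda_enabled` and
#' an E population.
#'
#' @param config An `eiphase_config` (or plain list with the same fields).
#' @return The validated configuration.
#' @export
validate_config <- function(config) {
  cfg <- config
  bad <- character()
  chk <- function(cond, key) if (!cond) bad <<- c(bad, key)
  chk(cfg$n_e >= 0, "n_e")
  chk(cfg$n_i >= 1, "n_i")
  chk(cfg$n_e >= 1 || cfg$topology == "II_only", "n_e")
  chk(cfg$p_conn >= 0 && cfg$p_conn <= 1, "p_conn")
  chk(cfg$dt_ms > 0, "dt_ms")
  chk(cfg$duration_ms >= 0, "duration_ms")
  chk(cfg$warmup_ms >= 0 && cfg$warmup_ms <= cfg$duration_ms, "warmup_ms")
  for (k in c("g_ee", "g_ei", "g_ie", "g_ii", "g_nmda", "g_bg_e", "g_bg_i"))
    chk(cfg[[k]] >= 0, k)
  chk(cfg$nu_e >= 0, "nu_e"); chk(cfg$nu_i >= 0, "nu_i")
  if (cfg$topology == "EI_only") {
    chk(cfg$g_ee == 0, "g_ee"); chk(cfg$g_ii == 0, "g_ii")
    chk(!cfg$nmda_enabled, "nmda_enabled")
  }
  if (cfg$topology == "II_only") {
    chk(cfg$g_ee == 0, "g_ee"); chk(cfg$g_ei == 0, "g_ei")
    chk(!cfg$nmda_enabled, "nmda_enabled")
  }
  if (cfg$nmda_enabled) chk(cfg$n_e > 0, "n_e")
  if (length(bad))
    abort(paste0("invalid configuration: ", paste(unique(bad),
                                                  collapse = ", ")))
  cfg
}

#' @export
print.eiphase_config <- function(x, ...) {
  cat("<eiphase_config> ", x$topology,
      sprintf(" %d E / %d I, p = %g, %g ms @ dt = %g ms, seed %d\n",
              x$n_e, x$n_i, x$p_conn, x$duration_ms, x$dt_ms, x$seed))
  cat(sprintf("  g (uS): ee %g  ei %g  ie %g  ii %g  nmda %g (%s)\n",
              x$g_ee, x$g_ei, x$g_ie, x$g_ii, x$g_nmda,
              if (x$nmda_enabled) "on" else "off"))
  cat(sprintf("  background: %g kHz @ %g nS (E), %g kHz @ %g nS (I)\n",
              x$nu_e, x$g_bg_e, x$nu_i, x$g_bg_i))
  invisible(x)
}

sample_projection <- function(n_pre, n_post, p, same_pop) {
  if (n_pre == 0 || n_post == 0 || p == 0)
    return(list(pre = integer(), post = integer()))
  n_avail <- n_post - as.integer(same_pop)
  if (n_avail <= 0) return(list(pre = integer(), post = integer()))
  k <- rbinom(n_pre, n_avail, p)
  pre <- rep.int(seq_len(n_pre), k)
  post <- unlist(lapply(seq_len(n_pre), function(j) {
    if (k[j] == 0) return(integer())
    tgt <- sample.int(n_avail, k[j])
    if (same_pop) tgt <- ifelse(tgt >= j, tgt + 1L, tgt)
    tgt
  }), use.names = FALSE)
  list(pre = pre, post = as.integer(post))
}

#' Build the random connectivity
#'
#' Each ordered pair of neurons (excluding self-pairs) is connected
#' independently with probability `p_conn`; projections forbidden by the
#' topology are empty. The generator seeds the R random stream with
#' `config$seed` unless `reseed = FALSE` (used internally by
#' [simulate_network()], which manages the stream itself), so a given
#' configuration always yields the same graph.
#'
#' @param config An [network_config()].
#' @param reseed Seed the RNG with `config$seed` first.
#' @return List of class `eiphase_connectivity` with per-projection
#'   `pre`/`post` integer vectors (1-based) under `ee`, `ei`, `ie`, `ii`.
#' @export
build_connectivity <- function(config, reseed = TRUE) {
  cfg <- validate_config(config)
  if (reseed) set.seed(cfg$seed)
  allow <- switch(cfg$topology,
    combined = c(ee = TRUE, ei = TRUE, ie = TRUE, ii = TRUE),
    EI_only  = c(ee = FALSE, ei = TRUE, ie = TRUE, ii = FALSE),
    II_only  = c(ee = FALSE, ei = FALSE, ie = TRUE, ii = TRUE))
  empty <- list(pre = integer(), post = integer())
  conn <- list(
    ee = if (allow["ee"]) sample_projection(cfg$n_e, cfg$n_e, cfg$p_conn,
                                            TRUE) else empty,
    ei = if (allow["ei"]) sample_projection(cfg$n_e, cfg$n_i, cfg$p_conn,
                                            FALSE) else empty,
    ie = if (allow["ie"]) sample_projection(cfg$n_i, cfg$n_e, cfg$p_conn,
                                            FALSE) else empty,
    ii = if (allow["ii"]) sample_projection(cfg$n_i, cfg$n_i, cfg$p_conn,
                                            TRUE) else empty)
  structure(conn, class = c("eiphase_connectivity", "list"),
            n_e = cfg$n_e, n_i = cfg$n_i)
}

#' Edge table of a connectivity object
#'
#' @param conn An `eiphase_connectivity`.
#' @return Tibble with columns `projection`, `pre`, `post`.
#' @export
connectivity_edges <- function(conn) {
  stopifnot(inherits(conn, "eiphase_connectivity"))
  purrr::map_dfr(c("ee", "ei", "ie", "ii"), function(pj) {
    tibble::tibble(projection = pj, pre = conn[[pj]]$pre,
                   post = conn[[pj]]$post)
  })
}

#' Realized edge density per projection
#'
#' Realized directed-edge count divided by the number of admissible ordered
#' pairs (self-pairs excluded within a population).
#'
#' @param conn An `eiphase_connectivity`.
#' @return Tibble with `projection`, `n_edges`, `n_pairs`, `density`.
#' @export
connectivity_density <- function(conn) {
  stopifnot(inherits(conn, "eiphase_connectivity"))
  n_e <- attr(conn, "n_e"); n_i <- attr(conn, "n_i")
  pairs <- c(ee = n_e * (n_e - 1), ei = n_e * n_i, ie = n_i * n_e,
             ii = n_i * (n_i - 1))
  purrr::map_dfr(c("ee", "ei", "ie", "ii"), function(pj) {
    tibble::tibble(projection = pj,
                   n_edges = length(conn[[pj]]$pre),
                   n_pairs = max(pairs[pj], 0),
                   density = ifelse(pairs[pj] > 0,
                                    length(conn[[pj]]$pre) / pairs[pj],
                                    NA_real_))
  })
}

#' Scale a scenario to a smaller network
#'
#' Divides the population sizes by `factor` and multiplies the
#' per-connection recurrent conductances by the same factor, preserving the
#' mean synaptic drive per neuron so the oscillation regime carries over to
#' desk-scale runs. Background conductances are per-neuron and are left
#' unchanged.
#'
#' @param config An [network_config()].
#' @param factor Size reduction factor (> 1 shrinks).
#' @return Rescaled configuration.
#' @export
scale_scenario <- function(config, factor) {
  stopifnot(factor > 0)
  cfg <- config
  cfg$n_e <- as.integer(round(cfg$n_e / factor))
  cfg$n_i <- as.integer(round(cfg$n_i / factor))
  for (k in c("g_ee", "g_ei", "g_ie", "g_ii", "g_nmda"))
    cfg[[k]] <- cfg[[k]] * factor
  if (!is.null(cfg$label)) cfg$label <- paste0(cfg$label, "_x", factor)
  validate_config(cfg)
}

#' Write / read a configuration as YAML
#'
#' Round-trips the full configuration, including the cell and receptor
#' parameter sets, through a flat structured text file.
#'
#' @param config An [network_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   restored configuration.
#' @export
write_config <- function(config, path) {
  cfg <- validate_config(config)
  plain <- rapply(unclass(cfg), function(x)
    if (is.numeric(x) && any(!is.finite(x))) "Inf" else x,
    how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- rapply(raw, function(x) if (identical(x, "Inf")) Inf else x,
                how = "replace")
  cfg <- raw
  cfg$n_e <- as.integer(cfg$n_e); cfg$n_i <- as.integer(cfg$n_i)
  cfg$seed <- as.integer(cfg$seed)
  cfg$interneuron <- do.call(interneuron_params, cfg$interneuron)
  cfg$pyramidal <- do.call(pyramidal_params, cfg$pyramidal)
  cfg$kinetics <- do.call(receptor_kinetics, cfg$kinetics)
  class(cfg) <- c("eiphase_config", "list")
  validate_config(cfg)
}
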
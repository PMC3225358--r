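#' Default model configuration
#'
#' Returns the full parameter block of the model as a nested list.  All
#' units are fixed: potentials in mV, capacitance in nF, conductances in
#' nS, times in ms, transmitter concentration in mM, rates in Hz, currents
#' in pA.  Synaptic weights are dimensionless multipliers on the receptor
#' maximal conductances.
#'
#' Weight parameters (`w_E`, `w_I`, `w_chain`) are expressed for the
#' reference pool size of 500 neurons; when a network is built with a
#' smaller pool (e.g. the 100-neuron test profile) they are rescaled by
#' `reference_size / pool_size` so that the total recurrent drive per
#' neuron, and hence the pool dynamics, stay comparable.
#'
#' @param pool_size neurons per pool (default 500).
#' @param ... named overrides merged into the defaults; nested blocks can
#'   be replaced wholesale or partially (via [utils::modifyList()]
#'   semantics).
#' @return a nested list of class `chain_config`.
#' @examples
#' cfg <- default_config(pool_size = 100)
#' cfg$topology$inh_fraction
#' @export
default_config <- function(pool_size = 500, ...) {
  cfg <- list(
    neuron = list(
      V_L = -70, V_thr = -50, V_reset = -60,
      C_m = 0.5, g_L = 25, tau_ref = 2
    ),
    receptors = list(
      ampa_ext = list(g_max = 6.0, E_rev = 0,   alpha = 1.1,   beta = 0.19),
      ampa_rec = list(g_max = 1.0, E_rev = 0,   alpha = 1.1,   beta = 0.19),
      nmda     = list(g_max = 0.5, E_rev = 0,   alpha = 0.072, beta = 0.0066,
                      Mg = 1, mg_K = 3.57, mg_gamma = 0.062),
      gaba     = list(g_max = 1.0, E_rev = -70, alpha = 5.0,   beta = 0.18),
      T_amp = 1, T_dur = 1
    ),
    topology = list(
      pool_size = pool_size, reference_size = 500,
      inh_fraction = 0.25, p_intra = 0.20, p_inter = 0.10,
      w_E = 1.6, w_I = 8.0, w_chain = 0.26
    ),
    integration = list(dt = 0.1),
    stimulus = list(
      # channel weights multiply g_max of the external AMPA receptor
      channel_weights = c(pfc = 12.0, tonic = 2.2, sensory = 2.4, motor = 1.8),
      intention = list(peak_rate = 400, width = 150, fraction = 0.20),
      feedback  = list(rate = 200, duration = 300, fraction = 0.50,
                       fraction_corollary = 1.0, rate_corollary = 300),
      pfc_tonic = list(rate = 150, fraction = 0.20),
      template  = list(n_acts = 4, burst_duration = 300, overlap = 80,
                       peak_rate = 60, filter_sigma = 20, baseline = 10,
                       margin = 310)
    ),
    engine = list(bin = 20, rate_floor = 20, act_duration = 300,
                  sensory_lead = 80),
    plasticity = list(
      eta = 0.4, A_plus = 1, A_minus = 1,
      tau_plus = 20, tau_minus = 20,
      tau_E = 500, u = 0.2, w_min = 0, w_max = 5,
      pairing = "nearest", w_init = c(0.01, 0.05)
    )
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
  class(cfg) <- c("chain_config", "list")
  cfg
}

validate_config <- function(cfg) {
  top <- cfg$topology
  stopifnot(
    top$pool_size >= 2,
    top$inh_fraction >= 0, top$inh_fraction <= 1,
    top$p_intra >= 0, top$p_intra <= 1,
    top$p_inter >= 0, top$p_inter <= 1,
    cfg$integration$dt > 0,
    cfg$neuron$V_reset < cfg$neuron$V_thr,
    cfg$neuron$C_m > 0, cfg$neuron$g_L > 0, cfg$neuron$tau_ref >= 0,
    cfg$engine$bin > 0
  )
  for (k in c("ampa_ext", "ampa_rec", "nmda", "gaba")) {
    r <- cfg$receptors[[k]]
    stopifnot(r$g_max >= 0, r$alpha > 0, r$beta > 0)
  }
  if (cfg$receptors$nmda$Mg < 0)
    stop("magnesium concentration must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a `chain_config` list.
#' @return `read_config()` returns a validated `chain_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cw <- raw$stimulus$channel_weights
  if (!is.null(cw)) raw$stimulus$channel_weights <- unlist(cw)
  cfg <- utils::modifyList(default_config(), raw)
  validate_config(cfg)
  class(cfg) <- c("chain_config", "list")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$stimulus$channel_weights <- as.list(x$stimulus$channel_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))
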
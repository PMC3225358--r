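# Shared fixtures: small configurations, an R reference integrator for the
# single-neuron path through the C++ engine, and a brute-force STDP oracle.

test_config <- function(...) default_config(pool_size = 100, ...)

one_pool_net <- function(seed = 1, cfg = test_config()) {
  build_network(cfg, chains = list(p = "act"), seed = seed)
}

# Closed-form solutions used as oracles
passive_decay <- function(V0, V_L, tau_m, t) V_L + (V0 - V_L) * exp(-t / tau_m)
gating_decay <- function(s0, beta, t) s0 * exp(-beta * t)
gating_fixed_point <- function(alpha, T_conc, beta) {
  alpha * T_conc / (alpha * T_conc + beta)
}
efficacy_recovery <- function(E0, tau_E, t) 1 - (1 - E0) * exp(-t / tau_E)

# Brute-force all-pairs STDP oracle: explicit double loop over spike pairs,
# exact exponential efficacy recovery; mirrors the event ordering of the
# engine (per later spike: potentiation on in-edges, then depression on
# out-edges) but computes every pairing by direct summation.
brute_stdp <- function(edges, spikes, par) {
  w <- edges$w
  n_sp <- nrow(spikes)
  sp_by_neuron <- split(spikes$t, spikes$neuron)
  eff_at <- function(i, t) {
    st <- sp_by_neuron[[as.character(i)]]
    st <- st[st < t]
    if (!length(st)) return(1)
    E <- 1
    for (k in seq_along(st)) {
      if (k > 1) E <- 1 - (1 - E) * exp(-(st[k] - st[k - 1]) / par$tau_E)
      E <- E * (1 - par$u)
    }
    1 - (1 - E) * exp(-(t - st[length(st)]) / par$tau_E)
  }
  for (s in seq_len(n_sp)) {
    t <- spikes$t[s]; j <- spikes$neuron[s]
    for (e in which(edges$post == j)) {
      i <- edges$pre[e]
      t_pre <- sp_by_neuron[[as.character(i)]]
      t_pre <- t_pre[t_pre < t]
      if (!length(t_pre)) next
      x <- sum(exp(-(t - t_pre) / par$tau_plus))
      w[e] <- min(par$w_max, max(par$w_min,
                  w[e] + par$eta * eff_at(i, t) * par$A_plus * x))
    }
    for (e in which(edges$pre == j)) {
      k <- edges$post[e]
      t_post <- sp_by_neuron[[as.character(k)]]
      t_post <- t_post[t_post < t]
      if (!length(t_post)) next
      x <- sum(exp(-(t - t_post) / par$tau_minus))
      w[e] <- min(par$w_max, max(par$w_min,
                  w[e] - par$eta * eff_at(j, t) * par$A_minus * x))
    }
  }
  w
}

# R reference run of one unconnected neuron driven by external spikes on the
# pfc channel, reproducing the engine's per-step order: consume pulses,
# currents from start-of-step V and s, membrane step, gating step.
r_reference_neuron <- function(ext_times, duration, cfg = test_config()) {
  dt <- cfg$integration$dt
  np <- neuron_params(cfg$neuron$V_L, cfg$neuron$V_thr, cfg$neuron$V_reset,
                      cfg$neuron$C_m, cfg$neuron$g_L, cfg$neuron$tau_ref)
  r <- cfg$receptors$ampa_ext
  chw <- cfg$stimulus$channel_weights[["pfc"]]
  rp <- receptor_params("AMPA_ext", g_max = r$g_max, E_rev = r$E_rev,
                        alpha = r$alpha, beta = r$beta,
                        T_amp = cfg$receptors$T_amp, T_dur = cfg$receptors$T_dur)
  st <- list(V = np$V_L, refr_remaining = 0)
  s <- 0; pulse_end <- -Inf
  ptr <- 1L
  spikes <- numeric()
  Vtrace <- numeric()
  n_steps <- round(duration / dt)
  for (k in seq_len(n_steps) - 1L) {
    t <- k * dt
    while (ptr <= length(ext_times) && ext_times[ptr] < t + dt) {
      pulse_end <- ext_times[ptr] + rp$T_dur
      ptr <- ptr + 1L
    }
    I <- receptor_current(s, chw, st$V, rp)
    out <- step_membrane(st, np, I, dt)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, t + dt)
    T_now <- if (pulse_end > t) rp$T_amp else 0
    s <- update_gating(s, T_now, rp$alpha, rp$beta, dt)
    Vtrace[k + 1L] <- st$V
  }
  list(V = Vtrace, spikes = spikes)
}

# The same neuron through the C++ engine: a 2-neuron pool with no local
# wiring, external spikes injected on the pfc channel at neuron 1.
cpp_reference_neuron <- function(ext_times, duration, cfg = test_config()) {
  cfg$topology$pool_size <- 2
  cfg$topology$p_intra <- 0
  cfg$topology$reference_size <- 2  # no weight rescaling
  net <- build_network(cfg, chains = list(p = "act"), seed = 1)
  netc <- chainsim:::net_cstruct_(net)
  state <- chainsim:::init_state_(net)
  ext <- lapply(chainsim:::channel_index_,
                function(c) list(t = numeric(), id = integer()))
  ext$pfc <- list(t = ext_times, id = rep(1L, length(ext_times)))
  out <- chainsim:::cpp_run_chunk(netc, state, ext, 0,
                                  round(duration / cfg$integration$dt),
                                  cfg$integration$dt, FALSE)
  sel <- out$spike_id == 1L
  list(spikes = out$spike_t[sel], V = out$state$V[1])
}
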
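# Orchestration of the closed-loop simulations: the chunked stepping loop,
# online pool-activation detection, and the motor / ambiguous / visual task
# protocols.

csc_parts_ <- function(W) {
  W <- methods::as(W, "CsparseMatrix")
  list(p = W@p, i = W@i, x = W@x)
}

net_cstruct_ <- function(network) {
  cfg <- network$config
  r <- cfg$receptors
  le <- csc_parts_(network$W_local_E)
  li <- csc_parts_(network$W_local_I)
  wi <- csc_parts_(network$W_inter)
  pool_of <- integer(network$n)
  for (p in seq_len(nrow(network$pools)))
    pool_of[seq.int(network$pools$from[p], network$pools$to[p])] <- p - 1L
  list(
    n = network$n, pool_of = pool_of, n_pools = nrow(network$pools),
    WleP = le$p, WleI = le$i, WleX = le$x,
    WliP = li$p, WliI = li$i, WliX = li$x,
    WinP = wi$p, WinI = wi$i, WinX = wi$x,
    VL = cfg$neuron$V_L, Vthr = cfg$neuron$V_thr, Vreset = cfg$neuron$V_reset,
    C_m = cfg$neuron$C_m, gL = cfg$neuron$g_L, tauref = cfg$neuron$tau_ref,
    g_ampa = r$ampa_rec$g_max, a_ampa = r$ampa_rec$alpha, b_ampa = r$ampa_rec$beta,
    g_nmda = r$nmda$g_max, a_nmda = r$nmda$alpha, b_nmda = r$nmda$beta,
    Mg = r$nmda$Mg, mgK = r$nmda$mg_K, mgGamma = r$nmda$mg_gamma,
    g_gaba = r$gaba$g_max, E_gaba = r$gaba$E_rev,
    a_gaba = r$gaba$alpha, b_gaba = r$gaba$beta,
    g_ext = r$ampa_ext$g_max,
    chw = unname(cfg$stimulus$channel_weights[names(channel_index_)]),
    Tamp = r$T_amp, Tdur = r$T_dur
  )
}

init_state_ <- function(network) {
  n <- network$n
  nc <- length(channel_index_)
  list(V = rep(network$config$neuron$V_L, n),
       s_ampa = numeric(n), s_nmda = numeric(n), s_gaba = numeric(n),
       s_ext = matrix(0, nc, n),
       pulse_end = rep(-Inf, n), ext_pulse_end = matrix(-Inf, nc, n),
       refr = numeric(n))
}

channel_index_ <- c(pfc = 1L, tonic = 2L, sensory = 3L, motor = 4L)

#' Simulate a network under a stimulus program
#'
#' Chunked fixed-step simulation: the network is advanced one PSTH bin at
#' a time; after each bin the per-pool population rate is computed and,
#' when a `controller` is supplied, pool-activation events are detected
#' online and the controller may schedule further stimulus events
#' (feedback contingent on activation, disambiguation, observation).
#'
#' A pool counts as *activated* in a bin when its binned rate reaches both
#' the absolute floor (`config$engine$rate_floor`, default 20 Hz) and half
#' of its running peak rate.
#'
#' @param network a `chain_network`.
#' @param events list of [stimulus_event()]s scheduled up front.
#' @param duration simulated time, ms.
#' @param seed RNG seed for all stimulus sampling during the run.
#' @param controller optional list of callbacks:
#'   `on_activation(pool_id, t, ctx)` returning a (possibly empty) list of
#'   new stimulus events; `ctx` carries the network and scenario fields.
#' @param motor_gate `"open"` (activations of chain pools are emitted as
#'   motor-output events) or `"closed"` (the inhibitory gate after
#'   premotor cortex: activations are recorded as suppressed, no motor
#'   output).
#' @param scenario free-form list stored in the result manifest.
#' @param record_currents record the per-pool decomposition of the input
#'   current (previous pool / local E / local I / PFC / sensory / motor).
#' @return a `chain_sim_result`: `raster` (neuron, pool, t), `pool_rates`
#'   (bins x pools, Hz), `bursts`, `activations`, `motor_events`,
#'   `outcome`, `currents`, `manifest`.
#' @export
simulate_network <- function(network, events = list(), duration = 1000,
                             seed = 1, controller = NULL,
                             motor_gate = c("open", "closed"),
                             scenario = list(), record_currents = FALSE) {
  motor_gate <- match.arg(motor_gate)
  cfg <- network$config
  bin <- cfg$engine$bin
  dt <- cfg$integration$dt
  steps_per_bin <- round(bin / dt)
  n_bins <- ceiling(duration / bin)
  netc <- net_cstruct_(network)
  state <- init_state_(network)
  n_pools <- nrow(network$pools)
  pool_sizes <- network$pools$size

  with_seed_(seed, {
    pending <- events
    sp_t <- vector("list", n_bins); sp_id <- vector("list", n_bins)
    rates <- matrix(0, n_bins, n_pools,
                    dimnames = list(NULL, network$pools$pool))
    cur_list <- if (record_currents) vector("list", n_bins) else NULL
    running_peak <- numeric(n_pools)
    activated_at <- rep(NA_real_, n_pools)
    motor_events <- list(); suppressed <- list()
    ctx <- list(network = network, scenario = scenario)

    for (b in seq_len(n_bins)) {
      t0 <- (b - 1) * bin; t1 <- b * bin
      ext <- lapply(channel_index_,
                    function(c) list(t = numeric(), id = integer()))
      for (ev in pending) {
        sp <- sample_event_spikes_(ev, t0, t1)
        if (nrow(sp)) {
          ci <- channel_index_[[ev$channel]]
          ext[[ci]]$t <- c(ext[[ci]]$t, sp$t)
          ext[[ci]]$id <- c(ext[[ci]]$id, sp$target)
        }
      }
      for (c in seq_along(ext)) {
        o <- order(ext[[c]]$t)
        ext[[c]]$t <- ext[[c]]$t[o]; ext[[c]]$id <- as.integer(ext[[c]]$id[o])
      }
      out <- cpp_run_chunk(netc, state, ext, t0, steps_per_bin, dt,
                           record_currents)
      state <- out$state
      sp_t[[b]] <- out$spike_t; sp_id[[b]] <- out$spike_id
      if (record_currents) cur_list[[b]] <- out$currents
      if (length(out$spike_id)) {
        cnt <- tabulate(netc$pool_of[out$spike_id] + 1L, n_pools)
        rates[b, ] <- cnt / (pool_sizes * bin / 1000)
      }
      running_peak <- pmax(running_peak, rates[b, ])
      newly <- which(is.na(activated_at) &
                     rates[b, ] >= cfg$engine$rate_floor &
                     rates[b, ] >= 0.5 * running_peak)
      for (p in newly) {
        activated_at[p] <- t1
        pid <- network$pools$pool[p]
        mev <- list(pool = pid, t = t1)
        if (motor_gate == "open") motor_events[[length(motor_events) + 1L]] <- mev
        else suppressed[[length(suppressed) + 1L]] <- mev
        if (!is.null(controller)) {
          nev <- controller$on_activation(pid, t1, ctx)
          if (length(nev)) pending <- c(pending, nev)
        }
      }
      # drop events that are over
      pending <- Filter(function(ev) ev$t_off > t1, pending)
    }

    raster <- data.frame(neuron = unlist(sp_id), t = unlist(sp_t))
    raster$pool <- network$pools$pool[netc$pool_of[raster$neuron] + 1L]
    raster <- raster[, c("neuron", "pool", "t")]

    bursts <- do.call(rbind, lapply(seq_len(n_pools), function(p) {
      d <- detect_pool_activation(rates[, p], bin = bin,
                                  floor = cfg$engine$rate_floor)
      if (nrow(d)) cbind(pool = network$pools$pool[p], d) else NULL
    }))
    if (is.null(bursts))
      bursts <- data.frame(pool = character(), onset = numeric(),
                           offset = numeric(), peak = numeric(),
                           duration = numeric())

    outcome <- outcome_from_activations_(network, activated_at)
    structure(list(
      raster = raster,
      pool_rates = rates,
      bin_time = seq_len(n_bins) * bin - bin / 2,
      bursts = bursts,
      activations = stats::setNames(activated_at, network$pools$pool),
      motor_events = motor_events,
      suppressed_motor = suppressed,
      outcome = outcome,
      currents = cur_list,
      manifest = list(seed = seed, duration = duration,
                      config_hash = config_hash(cfg),
                      motor_gate = motor_gate, scenario = scenario)
    ), class = "chain_sim_result")
  })
}

outcome_from_activations_ <- function(network, activated_at) {
  completed <- character(); halted <- character()
  for (cn in names(network$chains)) {
    cp <- paste(cn, network$chains[[cn]], sep = ".")
    cp <- cp[cp %in% network$pools$pool]
    if (!length(cp)) cp <- network$chains[[cn]]  # learning network pools
    act <- activated_at[match(cp, network$pools$pool)]
    if (all(!is.na(act))) completed <- c(completed, cn)
    else halted <- c(halted, cn)
  }
  list(completed_chains = completed, halted_chains = halted)
}

#' @export
print.chain_sim_result <- function(x, ...) {
  cat("<chain_sim_result> ", nrow(x$raster), " spikes, ",
      ncol(x$pool_rates), " pools, ", nrow(x$bursts), " burst(s)\n", sep = "")
  act <- x$activations[!is.na(x$activations)]
  if (length(act))
    cat("  activations: ",
        paste(sprintf("%s@%g ms", names(act), act), collapse = ", "),
        "\n", sep = "")
  cat("  completed: ", paste(x$outcome$completed_chains, collapse = ", "),
      " | halted: ", paste(x$outcome$halted_chains, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Detect activity bursts in a pool rate trace
#'
#' Bursts are the maximal runs of bins in which the binned population rate
#' is at least half the trace peak *and* at least the absolute floor.  A
#' flat (or everywhere sub-floor) trace yields an empty annotation table.
#'
#' @param rate_trace numeric vector of binned rates, Hz.
#' @param bin bin width, ms.
#' @param floor absolute rate floor, Hz.
#' @return data.frame with `onset`, `offset` (ms), `peak` (Hz),
#'   `duration` (ms), one row per burst in temporal order.
#' @export
detect_pool_activation <- function(rate_trace, bin = 20, floor = 20) {
  stopifnot(bin > 0)
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      peak = numeric(), duration = numeric())
  if (!length(rate_trace) || max(rate_trace) < floor) return(empty)
  thr <- max(0.5 * max(rate_trace), floor)
  above <- rate_trace >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  do.call(rbind, lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    data.frame(onset = (i0 - 1) * bin, offset = i1 * bin,
               peak = max(rate_trace[i0:i1]), duration = (i1 - i0 + 1) * bin)
  }))
}

# --- task protocols ---------------------------------------------------------

# Controller used by the motor and ambiguous tasks: on activation of pool k
# of a chain, deliver corollary discharge to it for act_duration and, as the
# act draws to completion, sensory feedback to pool k+1 (unless vetoed by
# `allow_next`).  The sensory event starts `sensory_lead` ms before act
# completion so that successive pool bursts overlap, as they do in vivo.
execution_controller_ <- function(network, act_duration, sensory_enabled,
                                  allow_next = function(chain, k) TRUE) {
  fb <- network$config$stimulus$feedback
  lead <- min(network$config$engine$sensory_lead, act_duration / 2)
  list(on_activation = function(pool_id, t, ctx) {
    p <- match(pool_id, network$pools$pool)
    cn <- network$pools$chain[p]
    acts <- network$chains[[cn]]
    k <- match(network$pools$motor_act[p], acts)
    evs <- list(gen_feedback_train(network, "corollary", pool_id,
                                   onset = t, duration = act_duration))
    if (sensory_enabled && !is.na(k) && k < length(acts) &&
        allow_next(cn, k)) {
      next_pool <- paste(cn, acts[k + 1L], sep = ".")
      evs <- c(evs, list(gen_feedback_train(network, "sensory", next_pool,
                                            onset = t + act_duration - lead,
                                            duration = fb$duration)))
    }
    evs
  })
}

#' Run the motor task (Simulation 1)
#'
#' The prefrontal intention burst ignites the first pool of the selected
#' chain at t = 0.  When a pool's activation is detected, motor corollary
#' discharge sustains it for `act_duration`; at act completion, sensory
#' feedback is delivered to the next pool of the chain.  Because input
#' from the preceding pool alone is subthreshold, the burst propagates one
#' act at a time, locked to these external events, and halts (without
#' error) if the required feedback never arrives.
#'
#' @param network a `chain_network`.
#' @param goal chain id to execute.
#' @param act_duration duration of each motor act, ms; stretching it
#'   stretches the whole propagation timeline without reconfiguring the
#'   network.
#' @param duration total simulated time, ms; defaults to generous room for
#'   the full chain.
#' @param seed RNG seed.
#' @param sensory_enabled set `FALSE` to withhold all sensory feedback
#'   (the chain then halts after the first pool).
#' @param record_currents see [simulate_network()].
#' @return a `chain_sim_result`.
#' @export
run_motor_task <- function(network, goal = names(network$chains)[1],
                           act_duration = NULL, duration = NULL, seed = 1,
                           sensory_enabled = TRUE, record_currents = FALSE) {
  if (!goal %in% names(network$chains)) stop("unknown chain: ", goal, call. = FALSE)
  act_duration <- act_duration %||% network$config$engine$act_duration
  n_acts <- length(network$chains[[goal]])
  duration <- duration %||% ((n_acts + 1.5) * act_duration + 400)
  first_pool <- paste(goal, network$chains[[goal]][1], sep = ".")
  burst <- gen_intention_burst(network, first_pool, seed = seed)
  ctl <- execution_controller_(network, act_duration, sensory_enabled)
  simulate_network(network, events = list(burst), duration = duration,
                   seed = seed, controller = ctl, motor_gate = "open",
                   scenario = list(mode = "motor", goal = goal,
                                   act_duration = act_duration,
                                   sensory_enabled = sensory_enabled),
                   record_currents = record_currents)
}

#' Run the ambiguous ("blind") task (Simulation 2)
#'
#' The target object is hidden, so the intention module starts both chains
#' in parallel: their pools burst together through the shared prefix
#' (reaching, shaping, grasping).  At grasp completion the object is
#' recognized and the disambiguating sensory input reaches only the cued
#' chain's next pool; activity then propagates along the matching chain
#' and dies out in the other.
#'
#' @param network a two-chain `chain_network` whose chains share their act
#'   labels up to the penultimate act.
#' @param cue chain id revealed at disambiguation (e.g. `"eat"` when the
#'   hidden object turns out to be food).
#' @param act_duration,duration,seed,record_currents as in
#'   [run_motor_task()].
#' @return a `chain_sim_result`.
#' @export
run_ambiguous_task <- function(network, cue, act_duration = NULL,
                               duration = NULL, seed = 1,
                               record_currents = FALSE) {
  if (length(network$chains) < 2)
    stop("the ambiguous task needs at least two chains", call. = FALSE)
  if (!cue %in% names(network$chains)) stop("unknown cue: ", cue, call. = FALSE)
  lens <- lengths(network$chains)
  prefixes <- lapply(network$chains, function(a) a[seq_len(min(lens) - 1L)])
  if (length(unique(prefixes)) != 1L)
    stop("chains must share act labels up to the final act", call. = FALSE)
  act_duration <- act_duration %||% network$config$engine$act_duration
  n_acts <- max(lens)
  duration <- duration %||% ((n_acts + 1.5) * act_duration + 400)
  events <- with_seed_(seed, lapply(names(network$chains), function(cn)
    gen_intention_burst(network, paste(cn, network$chains[[cn]][1], sep = "."),
                        seed = NULL)))
  # sensory feedback into a chain's *final* pool only for the cued chain
  ctl <- execution_controller_(network, act_duration, TRUE,
    allow_next = function(chain, k) {
      final_step <- k + 1L == length(network$chains[[chain]])
      !final_step || chain == cue
    })
  simulate_network(network, events = events, duration = duration, seed = seed,
                   controller = ctl, motor_gate = "open",
                   scenario = list(mode = "ambiguous", cue = cue,
                                   act_duration = act_duration),
                   record_currents = record_currents)
}

#' Run the visual (action observation) task
#'
#' The same chains, used in recognition mode.  The prefrontal prediction
#' is a *subthreshold* tonic input to the first pool of the hypothesized
#' chain; observation events (hand configuration and motion, STS-like)
#' arrive act by act as the observed agent performs them, each targeting
#' the pools coding the observed act.  A pool ignites only when chain
#' input (or the PFC prediction, for the first pool) coincides with the
#' matching observation, so an observed goal switch silences the chain at
#' the mismatched act.  The inhibitory gate after premotor cortex is
#' closed: no motor-output events are emitted.
#'
#' @param network a `chain_network`.
#' @param hypothesis chain id predicted by the observer.
#' @param observed character vector of observed motor acts in order;
#'   defaults to the hypothesized chain's own sequence (a matching
#'   observation).
#' @param act_duration duration of each observed act, ms.
#' @param duration,seed,record_currents as in [run_motor_task()].
#' @param obs_onset onset of the first observation event, ms.
#' @return a `chain_sim_result`; `motor_events` is empty by construction,
#'   would-be outputs are listed in `suppressed_motor`.
#' @export
run_visual_task <- function(network, hypothesis = names(network$chains)[1],
                            observed = NULL, act_duration = NULL,
                            duration = NULL, seed = 1, obs_onset = 100,
                            record_currents = FALSE) {
  if (!hypothesis %in% names(network$chains))
    stop("unknown chain: ", hypothesis, call. = FALSE)
  acts <- network$chains[[hypothesis]]
  observed <- observed %||% acts
  act_duration <- act_duration %||% network$config$engine$act_duration
  duration <- duration %||% (obs_onset + (length(observed) + 1) * act_duration + 400)
  ton <- network$config$stimulus$pfc_tonic
  fb <- network$config$stimulus$feedback
  first_pool <- paste(hypothesis, acts[1], sep = ".")
  events <- with_seed_(seed, {
    k <- max(1L, round(ton$fraction * length(pool_neurons(network, first_pool))))
    ids <- pool_neurons(network, first_pool, type = "excitatory")
    k <- min(k, length(ids))
    evs <- list(stimulus_event("tonic", sort(sample(ids, k)),
                               t_on = 0, t_off = duration,
                               rate = ton$rate, peak_rate = ton$rate,
                               label = "prediction"))
    lead <- min(network$config$engine$sensory_lead, act_duration / 2)
    for (m in seq_along(observed)) {
      # visual information about act m begins slightly before the nominal
      # act boundary (observed movements are continuous), giving successive
      # pool bursts the same overlap as in execution
      onset <- obs_onset + (m - 1) * act_duration - (if (m > 1) lead else 0)
      # the observation of act m reaches the pool coding that act, in every
      # chain where it sits at the observed position of the sequence
      for (cn in names(network$chains)) {
        acts_c <- network$chains[[cn]]
        if (m > length(acts_c) || !identical(acts_c[m], observed[m])) next
        evs <- c(evs, list(
          gen_feedback_train(network, "sensory", paste(cn, acts_c[m], sep = "."),
                             onset = onset, duration = act_duration + lead,
                             rate = fb$rate, fraction = fb$fraction,
                             seed = NULL)))
      }
    }
    evs
  })
  simulate_network(network, events = events, duration = duration, seed = seed,
                   controller = NULL, motor_gate = "closed",
                   scenario = list(mode = "visual", hypothesis = hypothesis,
                                   observed = observed,
                                   act_duration = act_duration),
                   record_currents = record_currents)
}

#' Map the operating regime of a pool (excitation/inhibition sweep)
#'
#' For each combination of local excitatory and inhibitory weight, one
#' isolated pool is built, probed with the standard brief intention burst,
#' and classified by the response of its *non-stimulated* neurons (the
#' directly targeted 20% fire by construction, so recruitment of the rest
#' is what distinguishes the regimes):
#' \describe{
#'   \item{silent}{the rest of the pool is never recruited above the floor;}
#'   \item{transient}{an avalanche recruits the pool but activity returns
#'     to near zero before the end of the window;}
#'   \item{sustained}{recruited activity persists to the end of the window
#'     (the non-transient regime to avoid).}
#' }
#' The default `(w_E, w_I)` of the configuration must fall in the
#' transient region.
#'
#' @param config a [default_config()]; `w_E`/`w_I` grids are in the same
#'   reference-size units as `config$topology`.
#' @param w_E_grid,w_I_grid weight grids to sweep.
#' @param duration window length, ms.
#' @param seed RNG seed (same seed for every grid point).
#' @return data.frame with `w_E`, `w_I`, `regime` (factor
#'   silent < transient < sustained), `peak` and `tail` rates (Hz) of the
#'   non-stimulated sub-population.
#' @export
calibrate_pool_regime <- function(config = default_config(),
                                  w_E_grid, w_I_grid,
                                  duration = 1200, seed = 1) {
  stopifnot(all(w_E_grid >= 0), all(w_I_grid >= 0))
  floor_hz <- config$engine$rate_floor
  bin <- config$engine$bin
  grid <- expand.grid(w_E = w_E_grid, w_I = w_I_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$topology$w_E <- grid$w_E[g]
    cfg$topology$w_I <- grid$w_I[g]
    net <- build_network(cfg, chains = list(probe = "act"), seed = seed)
    burst <- gen_intention_burst(net, "probe.act", seed = seed)
    sim <- simulate_network(net, events = list(burst), duration = duration,
                            seed = seed)
    others <- setdiff(pool_neurons(net, "probe.act"), burst$targets)
    sp <- sim$raster[sim$raster$neuron %in% others, ]
    n_bins <- nrow(sim$pool_rates)
    cnt <- if (nrow(sp)) tabulate(pmin(n_bins, floor(sp$t / bin) + 1L), n_bins)
           else integer(n_bins)
    rate <- cnt / (length(others) * bin / 1000)
    tail_rate <- mean(rate[(n_bins - round(100 / bin) + 1):n_bins])
    regime <- if (max(rate) < floor_hz) "silent"
      else if (tail_rate >= floor_hz) "sustained"
      else "transient"
    data.frame(w_E = grid$w_E[g], w_I = grid$w_I[g], regime = regime,
               peak = max(rate), tail = tail_rate)
  })
  out <- do.call(rbind, res)
  out$regime <- factor(out$regime, levels = c("silent", "transient", "sustained"),
                       ordered = TRUE)
  out
}
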
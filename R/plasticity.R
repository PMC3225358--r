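#' STDP parameters
#'
#' Parameters of the spike-timing-dependent plasticity rule with
#' activity-dependent synaptic efficacy.  A synapse is strengthened when
#' the postsynaptic neuron fires shortly after the presynaptic one and
#' weakened for the opposite order; each update is additionally scaled by
#' the (presynaptic) neuron's synaptic efficacy, which is depressed by a
#' fraction `u` at every spike of that neuron and recovers towards 1 with
#' time constant `tau_E`.
#'
#' @param eta learning rate.
#' @param A_plus,A_minus kernel maxima (default 1: the maximum amount of
#'   synaptic modification).
#' @param tau_plus,tau_minus kernel time constants, ms.
#' @param tau_E efficacy recovery time constant, ms.
#' @param u per-spike efficacy depression fraction.
#' @param w_min,w_max hard weight bounds.
#' @param pairing `"nearest"` (each spike pairs with the other neuron's
#'   most recent spike only) or `"all"` (all spike pairs contribute).
#' @return an `stdp_params` list.
#' @export
stdp_params <- function(eta = 0.005, A_plus = 1, A_minus = 1,
                        tau_plus = 20, tau_minus = 20,
                        tau_E = 500, u = 0.2, w_min = 0, w_max = 5,
                        pairing = c("nearest", "all")) {
  pairing <- match.arg(pairing)
  stopifnot(tau_plus > 0, tau_minus > 0, tau_E > 0, w_min >= 0,
            w_max > w_min, u >= 0, u < 1, eta >= 0)
  structure(list(eta = eta, A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 tau_E = tau_E, u = u, w_min = w_min, w_max = w_max,
                 pairing = pairing),
            class = "stdp_params")
}

#' STDP kernel
#'
#' Signed, exponentially decaying pairing kernel as a function of the
#' spike-time difference `dt = t_post - t_pre`:
#' \deqn{K(\Delta t) = A_+ e^{-\Delta t / \tau_+} \; (\Delta t > 0), \quad
#'       K(\Delta t) = -A_- e^{\Delta t / \tau_-} \; (\Delta t < 0)}
#' and `K(0) = 0` (a simultaneous pair is assigned to neither branch).
#' With the default amplitudes the maximum absolute modification is 1.
#'
#' @param dt_spike spike-time difference(s) `t_post - t_pre`, ms.
#' @param params an [stdp_params()] object.
#' @return signed kernel value(s).
#' @examples
#' stdp_kernel(20)    # exp(-1)
#' stdp_kernel(-20)   # -exp(-1)
#' @export
stdp_kernel <- function(dt_spike, params = stdp_params()) {
  stopifnot(all(is.finite(dt_spike)))
  ifelse(dt_spike > 0, params$A_plus * exp(-dt_spike / params$tau_plus),
         ifelse(dt_spike < 0, -params$A_minus * exp(dt_spike / params$tau_minus),
                0))
}

#' One update of the activity-dependent synaptic efficacy
#'
#' On a spike of the neuron the efficacy is depressed multiplicatively,
#' `E <- E (1 - u)`; otherwise it recovers towards 1 by one Euler step of
#' `dE/dt = (1 - E) / tau_E`.  `E` stays in (0, 1].
#'
#' @param E current efficacy value(s) in (0, 1].
#' @param spiked logical: did the neuron spike in this step?
#' @param dt step, ms.
#' @param params an [stdp_params()] object.
#' @return updated efficacy.
#' @export
update_efficacy <- function(E, spiked, dt, params = stdp_params()) {
  stopifnot(dt > 0)
  if (spiked) E * (1 - params$u)
  else pmin(1, E + dt * (1 - E) / params$tau_E)
}

# Edge-list representation of the plastic (inter-pool) synapses plus the
# CSR-style incidence indices the C++ event processor needs.
plastic_edges_ <- function(W, n) {
  s <- Matrix::summary(methods::as(W, "CsparseMatrix"))
  pre <- as.integer(s$j); post <- as.integer(s$i); w <- as.numeric(s$x)
  m <- length(pre)
  ord_in <- order(post); ord_out <- order(pre)
  in_p <- c(0L, cumsum(tabulate(post, n)))
  out_p <- c(0L, cumsum(tabulate(pre, n)))
  list(pre = pre - 1L, post = post - 1L, w = w, m = m,
       in_p = in_p, in_e = as.integer(ord_in - 1L),
       out_p = out_p, out_e = as.integer(ord_out - 1L))
}

edges_to_matrix_ <- function(ed, n) {
  methods::as(Matrix::sparseMatrix(i = ed$post + 1L, j = ed$pre + 1L,
                                   x = ed$w, dims = c(n, n)),
              "CsparseMatrix")
}

#' Apply STDP to a set of spike trains
#'
#' Event-driven application of the weight-update rule
#' \deqn{\Delta w_{ij} = \eta \, E_j(t) \, K(t_{post} - t_{pre})}
#' to the plastic synapses of a weight matrix, for a given list of spikes.
#' Efficacy is attached to the presynaptic neuron.  Under
#' `pairing = "all"` the result agrees with an explicit sum over all spike
#' pairs; `"nearest"` pairs each spike only with the other neuron's most
#' recent spike, which keeps updates bounded at high rates.
#'
#' @param W sparse plastic weight matrix (rows = post, cols = pre); only
#'   existing entries are updated (plasticity does not create synapses).
#' @param spikes data.frame with `t` (ms) and `neuron` (1-based ids),
#'   sorted by `t`.
#' @param n_neurons number of neurons spanned by `W`.
#' @param params an [stdp_params()] object.
#' @return the updated sparse weight matrix, clipped to
#'   `[w_min, w_max]` after every event.
#' @export
apply_weight_update <- function(W, spikes, n_neurons = nrow(W),
                                params = stdp_params()) {
  stopifnot(all(diff(spikes$t) >= 0))
  ed <- plastic_edges_(W, n_neurons)
  if (!ed$m || !nrow(spikes)) return(W)
  res <- cpp_stdp_run(ed$w, ed$pre, ed$post, ed$in_p, ed$in_e,
                      ed$out_p, ed$out_e,
                      as.numeric(spikes$t), as.integer(spikes$neuron),
                      as.integer(n_neurons),
                      params$eta, params$A_plus, params$A_minus,
                      params$tau_plus, params$tau_minus,
                      params$tau_E, params$u, params$w_min, params$w_max,
                      identical(params$pairing, "all"))
  ed$w <- res$w
  edges_to_matrix_(ed, n_neurons)
}

# Mean weight between two pools (pre pool a -> post pool b).
pool_weight_mean_ <- function(W, pools, a, b) {
  s <- Matrix::summary(methods::as(W, "CsparseMatrix"))
  sel <- s$j >= pools$from[a] & s$j <= pools$to[a] &
         s$i >= pools$from[b] & s$i <= pools$to[b]
  if (!any(sel)) return(NA_real_)
  mean(s$x[sel])
}

#' Chain learning experiment (Simulation 3)
#'
#' Starts from an all-to-all four-pool network with low random inter-pool
#' weights and trains it by repeatedly "executing" the action sequence:
#' in each session every pool is driven by its template activity profile
#' (four sequential ~300 ms bursts overlapping by ~80 ms, see
#' [gen_template_profiles()]), the resulting Poisson spike trains are fed
#' to the STDP rule, and the inter-pool weights are updated.  Because each
#' burst precedes the next, potentiation accumulates on forward
#' (k to k+1) synapses during the overlap windows while backward synapses
#' are depressed: the network is gradually hardwired into a feedforward
#' chain.
#'
#' At each requested checkpoint the network is probed by delivering the
#' standard intention burst to pool 1 alone (fixed probe seed, so probe
#' noise is identical across checkpoints) and the peak rates of all pools
#' are recorded.
#'
#' @param config a [default_config()] list.
#' @param sessions number of training sessions.
#' @param checkpoints session counts at which to probe (0 = before
#'   training); defaults to `c(0, 150, 250, 500)` clipped to `sessions`.
#' @param seed RNG seed for network construction and training spikes.
#' @param shuffle if `TRUE`, the assignment of template time slots to
#'   pools is randomly permuted in every session (control condition: no
#'   consistent temporal order, hence no consistent forward/backward
#'   asymmetry).
#' @param params an [stdp_params()]; defaults from `config$plasticity`.
#' @param probe_duration probe simulation window, ms.
#' @return list of class `chain_learning_result`: `checkpoints`,
#'   `probe_peaks` (checkpoints x pools matrix of peak rates, Hz),
#'   `weight_trace` (data.frame of mean forward/backward adjacent weights
#'   per checkpoint), `W_final`, `network`.
#' @export
run_learning_experiment <- function(config = default_config(),
                                    sessions = 500,
                                    checkpoints = NULL,
                                    seed = 1, shuffle = FALSE,
                                    params = NULL,
                                    probe_duration = 900) {
  stopifnot(sessions >= 1)
  pl <- config$plasticity
  params <- params %||% stdp_params(eta = pl$eta, A_plus = pl$A_plus,
                                    A_minus = pl$A_minus,
                                    tau_plus = pl$tau_plus,
                                    tau_minus = pl$tau_minus,
                                    tau_E = pl$tau_E, u = pl$u,
                                    w_min = pl$w_min, w_max = pl$w_max,
                                    pairing = pl$pairing)
  checkpoints <- sort(unique(pmin(checkpoints %||% c(0, 150, 250, 500),
                                  sessions)))
  net <- build_learning_network(config, seed = seed)
  n_pools <- nrow(net$pools)
  tp <- gen_template_profiles(config$stimulus$template)
  if (ncol(tp$rates) != n_pools)
    stop("template spec must provide one profile per pool", call. = FALSE)
  t_total <- max(tp$time)
  if (t_total < config$stimulus$template$burst_duration)
    stop("templates shorter than one burst", call. = FALSE)
  ed <- plastic_edges_(net$W_inter, net$n)

  probe <- function(W_now) {
    pn <- net
    pn$W_inter <- W_now
    burst <- gen_intention_burst(pn, net$pools$pool[1], seed = seed + 7L)
    sim <- simulate_network(pn, events = list(burst),
                            duration = probe_duration, seed = seed + 7L)
    apply(sim$pool_rates, 2, max)
  }
  wsum <- function(ed_now) {
    W <- edges_to_matrix_(ed_now, net$n)
    fw <- vapply(seq_len(n_pools - 1L), function(k)
      pool_weight_mean_(W, net$pools, k, k + 1L), 0)
    bw <- vapply(seq_len(n_pools - 1L), function(k)
      pool_weight_mean_(W, net$pools, k + 1L, k), 0)
    data.frame(pair = paste(seq_len(n_pools - 1L), seq(2, n_pools), sep = "->"),
               forward = fw, backward = bw)
  }

  probe_peaks <- matrix(NA_real_, length(checkpoints), n_pools,
                        dimnames = list(checkpoints, net$pools$pool))
  weight_trace <- list()

  with_seed_(seed, {
    ci <- 1L
    if (checkpoints[1] == 0) {
      probe_peaks[1, ] <- probe(edges_to_matrix_(ed, net$n))
      weight_trace[[1]] <- cbind(checkpoint = 0, wsum(ed))
      ci <- 2L
    }
    for (s in seq_len(max(checkpoints))) {
      slot <- if (shuffle) sample.int(n_pools) else seq_len(n_pools)
      # pool p is driven by the profile occupying time slot slot[p]
      spikes <- do.call(rbind, lapply(seq_len(n_pools), function(p) {
        ids <- seq.int(net$pools$from[p], net$pools$to[p])
        prof <- tp$rates[, slot[p]]
        rate_fn <- function(t) {
          idx <- pmax(1L, pmin(length(prof), floor(t) + 1L))
          prof[idx]
        }
        sp <- gen_poisson_train(rate_fn, t_total, length(ids),
                                rate_max = max(prof))
        if (nrow(sp)) data.frame(t = sp$t, neuron = ids[sp$train]) else NULL
      }))
      if (is.null(spikes) || !nrow(spikes)) next
      spikes <- spikes[order(spikes$t), ]
      res <- cpp_stdp_run(ed$w, ed$pre, ed$post, ed$in_p, ed$in_e,
                          ed$out_p, ed$out_e,
                          as.numeric(spikes$t), as.integer(spikes$neuron),
                          as.integer(net$n),
                          params$eta, params$A_plus, params$A_minus,
                          params$tau_plus, params$tau_minus,
                          params$tau_E, params$u, params$w_min, params$w_max,
                          identical(params$pairing, "all"))
      ed$w <- res$w
      if (ci <= length(checkpoints) && s == checkpoints[ci]) {
        probe_peaks[ci, ] <- probe(edges_to_matrix_(ed, net$n))
        weight_trace[[ci]] <- cbind(checkpoint = s, wsum(ed))
        ci <- ci + 1L
      }
    }
  })

  net$W_inter <- edges_to_matrix_(ed, net$n)
  structure(list(checkpoints = checkpoints,
                 probe_peaks = probe_peaks,
                 weight_trace = do.call(rbind, weight_trace),
                 W_final = net$W_inter,
                 network = net,
                 params = params, shuffle = shuffle, seed = seed),
            class = "chain_learning_result")
}

#' @export
print.chain_learning_result <- function(x, ...) {
  cat("<chain_learning_result> ", max(x$checkpoints), " sessions",
      if (x$shuffle) " (shuffled control)", "\n", sep = "")
  cat("probe peak rates (Hz):\n")
  print(round(x$probe_peaks, 1))
  wt <- x$weight_trace[x$weight_trace$checkpoint == max(x$checkpoints), ]
  cat("final mean adjacent weights:\n")
  print(wt, row.names = FALSE)
  invisible(x)
}
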
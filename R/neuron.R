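#' Neuron parameters
#'
#' Parameter block of the conductance-based leaky integrate-and-fire
#' neuron: below threshold the membrane obeys
#' \deqn{C_m \frac{dV}{dt} = -g_L (V - V_L) + I_{syn}(t)}
#' and when \eqn{V} reaches `V_thr` a spike is emitted, \eqn{V} is reset
#' to `V_reset` and held there for the refractory period `tau_ref`.
#'
#' @param V_L resting (leak) potential, mV.
#' @param V_thr firing threshold, mV.
#' @param V_reset reset potential, mV; must lie below `V_thr`.
#' @param C_m membrane capacitance, nF.
#' @param g_L leak conductance, nS.
#' @param tau_ref absolute refractory period, ms.
#' @return a `neuron_params` list; `tau_m = C_m / g_L` (in ms) is derived.
#' @export
neuron_params <- function(V_L = -70, V_thr = -50, V_reset = -60,
                          C_m = 0.5, g_L = 25, tau_ref = 2) {
  if (!(V_reset < V_thr)) stop("V_reset must be below V_thr", call. = FALSE)
  if (C_m <= 0 || g_L <= 0) stop("C_m and g_L must be positive", call. = FALSE)
  if (tau_ref < 0) stop("tau_ref must be non-negative", call. = FALSE)
  structure(list(V_L = V_L, V_thr = V_thr, V_reset = V_reset,
                 C_m = C_m, g_L = g_L, tau_ref = tau_ref,
                 tau_m = 1000 * C_m / g_L),
            class = "neuron_params")
}

#' Receptor channel parameters
#'
#' Kinetic receptor channel in the Destexhe single-exponential-pulse
#' formulation: the fraction of open receptors follows
#' \deqn{ds/dt = \alpha [T] (1 - s) - \beta s}
#' where the transmitter concentration \eqn{[T]} is a square pulse of
#' amplitude `T_amp` for `T_dur` ms after each presynaptic spike.  The
#' channel current is \eqn{I_X = -g_X (V - E_X) \sum_j w_j s_j}, with an
#' additional voltage-dependent magnesium unblock factor for NMDA.
#'
#' @param kind one of `"AMPA_ext"`, `"AMPA_rec"`, `"NMDA"`, `"GABA"`.
#' @param g_max maximal conductance, nS.
#' @param E_rev reversal potential, mV (0 for the glutamatergic channels,
#'   hyperpolarized for GABA).
#' @param alpha opening rate, 1/(mM ms).
#' @param beta closing rate, 1/ms.
#' @param T_amp,T_dur transmitter pulse concentration (mM) and duration (ms).
#' @param Mg external magnesium concentration, mM (NMDA only; 0 disables
#'   the block).
#' @return a `receptor_params` list.
#' @export
receptor_params <- function(kind = c("AMPA_ext", "AMPA_rec", "NMDA", "GABA"),
                            g_max, E_rev, alpha, beta,
                            T_amp = 1, T_dur = 1, Mg = 0) {
  kind <- match.arg(kind)
  if (g_max < 0) stop("g_max must be non-negative", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive", call. = FALSE)
  if (Mg < 0) stop("magnesium concentration must be non-negative", call. = FALSE)
  if (kind == "GABA" && E_rev > -40)
    warning("GABA reversal potential is expected to be hyperpolarized")
  structure(list(kind = kind, g_max = g_max, E_rev = E_rev,
                 alpha = alpha, beta = beta,
                 T_amp = T_amp, T_dur = T_dur, Mg = Mg),
            class = "receptor_params")
}

#' NMDA magnesium unblock factor
#'
#' Voltage dependence of the NMDA channel magnesium block, modelled as an
#' instantaneous function of the postsynaptic potential (Jahr-Stevens
#' form):
#' \deqn{B(V) = \frac{1}{1 + ([Mg]/K) e^{-\gamma V}}}
#' with \eqn{K = 3.57} mM and \eqn{\gamma = 0.062} /mV.  `B` is
#' monotonically increasing in `V`, tends to 1 as `V` grows, and is
#' identically 1 without magnesium.
#'
#' @param V membrane potential, mV (vectorized).
#' @param Mg external magnesium concentration, mM.
#' @param K,gamma block constants (mM, 1/mV).
#' @return unblock factor in (0, 1].
#' @examples
#' mg_block(0, 1)     # ~0.78
#' mg_block(-70, 1)   # strong block, ~0.04
#' @export
mg_block <- function(V, Mg = 1, K = 3.57, gamma = 0.062) {
  if (any(Mg < 0)) stop("magnesium concentration must be non-negative", call. = FALSE)
  1 / (1 + (Mg / K) * exp(-gamma * V))
}

#' One Euler step of the receptor gating equation
#'
#' Advances the open fraction `s` by one explicit Euler step of
#' \eqn{ds/dt = \alpha T (1-s) - \beta s}; the result is clipped to
#' \eqn{[0, 1]}.
#'
#' @param s current open fraction(s), in \[0, 1\].
#' @param T_conc transmitter concentration during the step, mM.
#' @param alpha,beta opening and closing rates.
#' @param dt step size, ms.
#' @return updated open fraction(s).
#' @export
update_gating <- function(s, T_conc, alpha, beta, dt) {
  stopifnot(dt > 0)
  s2 <- s + dt * (alpha * T_conc * (1 - s) - beta * s)
  pmin(1, pmax(0, s2))
}

#' Synaptic current through one receptor channel
#'
#' \deqn{I_X = -g_X (V - E_X) \sum_j w_j s_j}
#' in pA (positive = depolarizing), optionally multiplied by the magnesium
#' unblock factor [mg_block()] when `params$kind == "NMDA"`.
#'
#' @param s open fractions of the afferent receptors.
#' @param w afferent connection weights (same length as `s`).
#' @param V postsynaptic membrane potential, mV.
#' @param params a [receptor_params()] object.
#' @return current in pA.
#' @export
receptor_current <- function(s, w, V, params) {
  if (length(s) != length(w))
    stop("`s` and `w` must have the same length", call. = FALSE)
  drive <- sum(w * s)
  b <- if (params$kind == "NMDA") mg_block(V, params$Mg) else 1
  -params$g_max * b * (V - params$E_rev) * drive
}

#' One Euler step of the membrane equation
#'
#' If the neuron is refractory the potential is clamped to `V_reset` and
#' the refractory clock decremented; otherwise one explicit Euler step of
#' the leaky integrator is taken and a spike is emitted when the potential
#' reaches threshold (reset + refractory engage).
#'
#' @param state list with `V` (mV) and `refr_remaining` (ms).
#' @param params a [neuron_params()] object.
#' @param I_syn total synaptic current, pA.
#' @param dt step, ms.
#' @return list with the updated `state` and logical `spiked`.
#' @export
step_membrane <- function(state, params, I_syn, dt) {
  stopifnot(dt > 0)
  if (!is.finite(I_syn)) stop("non-finite synaptic current", call. = FALSE)
  spiked <- FALSE
  if (state$refr_remaining > 1e-12) {
    state$V <- params$V_reset
    state$refr_remaining <- max(0, state$refr_remaining - dt)
  } else {
    state$V <- state$V +
      dt * (-params$g_L * (state$V - params$V_L) + I_syn) / (1000 * params$C_m)
    if (state$V >= params$V_thr) {
      spiked <- TRUE
      state$V <- params$V_reset
      state$refr_remaining <- params$tau_ref
    }
  }
  list(state = state, spiked = spiked)
}
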
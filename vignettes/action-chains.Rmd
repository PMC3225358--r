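---
title: "Neuronal chains for goal-directed actions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal chains for goal-directed actions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainsim)
```

## The model

Neurons in the inferior parietal lobule code elementary goal-related motor
acts (reaching, shaping the hand, grasping, bringing to the mouth, placing),
and the same grasping neuron can fire differently depending on the final
goal of the sequence the act is embedded in.  `chainsim` implements the
hypothesis that this goal selectivity arises from *neuronal chains*: each
action goal owns a dedicated, unidirectional sequence of local pools, one
per motor act, and executing (or recognizing) an action is the propagation
of a burst of activity along the corresponding chain, paced by signals from
outside the parietal network.

### Neurons and synapses

Each neuron is a conductance-based leaky integrate-and-fire unit.  Below
threshold

$$C_m \frac{dV}{dt} = -g_L\,(V - V_L) + I_{syn}(t),$$

and when $V$ reaches $V_{thr}$ a spike is emitted, $V$ is reset to
$V_{reset}$ and clamped there for the refractory period.  The synaptic
current is the sum of glutamatergic (AMPA and NMDA) and GABAergic
components; each receptor type contributes

$$I_X = -g_X\,(V - E_X) \sum_j w_j\, s_j,$$

where $s_j$ is the open fraction of the receptors driven by afferent $j$,
integrated with first-order kinetics
$ds/dt = \alpha [T] (1 - s) - \beta s$ under a 1 mM / 1 ms transmitter
pulse per presynaptic spike (pulses from successive spikes extend rather
than stack).  The NMDA conductance is additionally multiplied by the
instantaneous magnesium unblock factor

$$B(V) = \frac{1}{1 + ([Mg]/3.57)\,e^{-0.062 V}}, \qquad [Mg] = 1\ \mathrm{mM},$$

which makes NMDA current negligible at rest and regenerative once a pool
depolarizes.  External inputs arrive through AMPA-type channels only;
recurrent excitation uses AMPA + NMDA; inhibition uses GABA$_A$.  Membrane
and kinetic constants are standard literature values (the parameter tables
of the original description are not machine-readable), all exposed in
`default_config()`: $V_L = -70$, $V_{thr} = -50$, $V_{reset} = -60$ mV,
$C_m = 0.5$ nF, $g_L = 25$ nS ($\tau_m = 20$ ms), refractory 2 ms; AMPA
$\alpha = 1.1$, $\beta = 0.19$; NMDA $\alpha = 0.072$, $\beta = 0.0066$;
GABA $\alpha = 5.0$, $\beta = 0.18$ (units 1/(mM·ms) and 1/ms).
Everything is advanced by explicit (first-order Euler) steps of
`dt = 0.1` ms; currents are evaluated from start-of-step voltages.  One
gating variable is kept per receptor type per *presynaptic* neuron — the
open fraction of afferent $j$ is the same quantity for every target, so
this is exact, not an approximation.

### Pools, chains, gating

A pool has 500 neurons by default, 25% of them inhibitory, and every neuron
receives local synapses from exactly 20% of its pool (exact fan-in; a fixed
percentage is stated, and degree-regular graphs make the count checks
exact).  Inhibitory neurons project only within their pool; excitatory
neurons also send long-range connections to the *next* pool of their chain
(never backwards).  Inter-pool links likewise use exact fan-in — each
target neuron receives from `round(p_inter * n_exc)` excitatory neurons of
the preceding pool (default `p_inter = 0.1`) — because a degree-regular
chain keeps the subthreshold chain input uniform across the target pool;
with binomially spread fan-in, the high tail of the degree distribution
intermittently broke the gating rule below.

The dynamical regime of a pool is set by the local weights `w_E` and
`w_I`.  `calibrate_pool_regime()` sweeps this plane, probes one pool with
the standard intention burst, and classifies the response of the
*non-stimulated* neurons as silent (never recruited), transient (an
avalanche that dies out), or sustained (activity persists to the end of
the window).  The classification uses the non-targeted sub-population
because the probe necessarily fires its direct targets — an avalanche
cannot start otherwise — so only recruitment distinguishes the regimes.
The defaults (`w_E = 1.6`, `w_I = 8.0`, in reference-size units) sit in
the transient region: an ignited pool produces a bell-shaped population
burst that collapses once its external drive ends, because the recurrent
excitation alone is not sufficient to latch against the recruited
inhibition.

Propagation is gated.  Chain input from the preceding pool alone
depolarizes the next pool only to a subthreshold level; the pool ignites
when that input coincides with an external signal (sensory feedback during
execution, observation input during recognition).  Concretely, at the
calibrated defaults the single-source equilibrium potentials sit several
mV below threshold, while two coincident sources push part of the pool
across threshold and local recurrence recruits the rest (the avalanche).
Because the network is noiseless apart from the stimulus trains, "silent"
states are genuinely silent, which makes the gating contract a hard
property rather than a statistical one.

### External signals

All external signals are seeded Poisson spike-train generators
(`gen_poisson_train()`, inhomogeneous profiles by thinning), delivered
over four channels with separate weights:

| signal | channel | default profile |
|---|---|---|
| intention burst (PFC) | `pfc` | Gaussian, peak 400 Hz, FWHM 150 ms, 20% of the first pool |
| prediction (visual mode) | `tonic` | constant 150 Hz, 20% of the first pool, subthreshold |
| sensory / observation | `sensory` | constant 200 Hz, 300 ms, 50% of the pool |
| motor corollary discharge | `motor` | constant 300 Hz, whole pool, during the act |

Stimulus targets are drawn from the excitatory neurons of a pool (target
counts are still fractions of the whole pool, e.g. 20% of 500 = 100).
This is the one structural choice that calibration forced: when external
events also drive pool interneurons directly, a ramped stimulus recruits
feedforward inhibition in lockstep with excitation and the avalanche never
triggers — a step ignites but a bell does not.  Long-range and
thalamocortical afferents contacting predominantly pyramidal cells is also
the standard physiological assumption.  The burst-mode and tonic-mode
prefrontal inputs use separate channels because a kinetic synapse's
per-spike conductance transient scales with the channel weight: one
channel cannot be both a strong trigger and a weak sustained bias.

### Task protocols

*Motor task.*  The intention burst ignites the first pool at $t = 0$.
Pool activation is detected online on 20 ms bins (rate at least the 20 Hz
floor and at least half the running peak — a rule that is scale-robust and
matches the histogram conventions used throughout).  On activation, motor
corollary discharge sustains the pool for `act_duration` (default 300 ms,
the duration of real reaching/grasping movements), and sensory feedback is
delivered to the next pool starting `sensory_lead = 80` ms before act
completion.  The lead reproduces the ~80 ms overlap of successive bursts
seen in the recordings this model emulates; with a zero-overlap handoff
the coincidence window reduces to the AMPA decay tail and propagation
fails intermittently.  Doubling `act_duration` stretches the whole
timeline without touching the network — timing lives in the external
events, not in the synapses.

*Ambiguous ("blind") task.*  Both goal chains receive the intention burst
and run in parallel through the shared prefix; at grasp completion the
disambiguating sensory input reaches only the cued chain's final pool, so
one chain completes and the other dies out.

*Visual task.*  The motor gate after premotor cortex is closed: pool
activations are recorded as suppressed, and `motor_events` stays empty by
construction.  The prefrontal prediction is tonic and subthreshold;
observation events arrive act by act (starting 80 ms before the nominal
act boundary, lasting `act_duration + 80` ms — observed movements are
continuous) and target the pools coding the observed act at its position
in the sequence.  A goal switch by the observed agent leaves the expected
pool without its observation input, and the chain halts at the mismatch.

### Plasticity and chain formation

The learning rule is spike-timing-dependent plasticity with an
activity-dependent synaptic efficacy:

$$\Delta w_{ij} = \eta\, E_j(t)\, K(t_{post} - t_{pre}), \qquad
K(\Delta t) = \begin{cases} A_+ e^{-\Delta t/\tau_+} & \Delta t > 0 \\
-A_- e^{\Delta t/\tau_-} & \Delta t < 0, \end{cases}$$

with $A_\pm = 1$ (the stated maximum modification), $\tau_\pm = 20$ ms,
$K(0) = 0$ (a simultaneous pair belongs to neither branch), hard bounds
$w \in [0, 5]$, and nearest-spike pairing by default (all-pairs mode
exists and is verified against a brute-force sum over spike pairs).  The
efficacy is attached to the presynaptic neuron, multiplied by $(1 - u)$,
$u = 0.2$, at each of its spikes and recovering toward 1 with
$\tau_E = 500$ ms — matching the short-term depression literature the
rule descends from.  The event-driven engine uses exact exponentials for
trace decay and efficacy recovery between events.

The chain-learning experiment starts from four pools connected all-to-all
with low random weights (uniform in [0.01, 0.05]) and "executes" the
sequence by driving each pool with a template activity profile: four
sequential bursts, 300 ms wide at half maximum, successive bursts
overlapping for 80 ms, Gaussian-filtered (20 ms), baseline-subtracted and
peak-normalized to 60 Hz (the template emulates smoothed in-vivo activity;
the normalization constant is not readable in the source and 60 Hz is a
typical parietal peak rate).  During training, pools are driven directly
by Poisson spikes drawn from these profiles and STDP is applied to the
inter-pool synapses; the membrane model is not simulated during training
because the templates *are* the prescribed activity.  Pairing traces and
efficacy reset between sessions (in vivo, sessions are minutes apart);
weights persist.  At checkpoints the network is probed by the standard
intention burst to pool 1 alone, with a fixed probe seed so that response
growth across checkpoints reflects the weights, not probe noise.

One default deviates from the obvious small-learning-rate convention:
$\eta = 0.4$.  With the efficacy term (which equilibrates near 0.14 at
template rates) and nearest-spike pairing, the net drift of an adjacent
forward weight is $\sim 5 \cdot 10^{-5} \eta$ per session; at
$\eta = 0.005$ nothing resembling a chain forms within the 150–500-session
protocol.  $\eta = 0.4$ was calibrated so that 150 sessions produce clear
partial propagation and 500 sessions near-saturated forward weights,
while backward weights collapse toward the lower bound.  Temporally
shuffled templates (the control) produce no consistent forward/backward
asymmetry.

## What the synthetic inputs do and do not show

All inputs are generated: there is no recorded data anywhere in the
pipeline.  The templates reproduce the *geometry* of the in-vivo bursts
(width, overlap, smoothing) but not their trial-to-trial variability,
rate irregularity, or correlations between neurons; the stimulus trains
are homogeneous or bell-shaped Poisson processes.  Passing tests
therefore demonstrate that the mechanisms — avalanche ignition,
subthreshold gating, externally paced propagation, STDP chain formation —
work as specified under these idealized drives, not that the model fits
any particular recorded dataset.

## Numerical and testing choices

* The test and acceptance profile uses 100-neuron pools; `w_E`, `w_I`,
  `w_chain` are rescaled by `reference_size / pool_size` at build time so
  per-neuron recurrent drive, and hence pool dynamics, match the 500-neuron
  reference.  Problem sizes in the suite (100-neuron pools, 150 learning
  sessions, 20-seed batteries, a 5x5 regime grid) were chosen as the
  smallest sizes at which every qualitative property is stable across
  seeds.
* Euler trajectories of the passive membrane, receptor gating and efficacy
  recovery are tested against their closed forms at `dt` and `dt/10`
  (first-order convergence); the C++ engine is tested spike-for-spike
  against an R composition of the exported single-neuron operations.
* Degenerate inputs (zero rates, empty rasters, flat traces, zero-width
  bursts, `w_E = 0`) return empty results or raise informative errors
  rather than propagating NaNs; gating variables are clipped to [0, 1];
  weights to their bounds after every event.
* Burst width and overlap are measured on 20 ms bins (the histogram
  convention used throughout), as time above half maximum; "overlap" is
  operationalized as joint time above both half-maxima.  The template
  geometry puts half-maximum crossings strictly inside bins, so the
  measured 300 ms / 80 ms are exact multiples of the bin.

## Known limitations

Single-compartment neurons; no conduction delays; no background noise
(gating is a hard threshold phenomenon here, where cortex would show a
noisy sigmoid); the prefrontal cue-to-chain association is configuration,
not learned; plasticity acts only on inter-pool synapses during the
learning experiment; the motor gate is a boolean sink rather than an
explicit premotor circuit; and the auditory modality, though it would ride
the same sensory channel, is exercised by no protocol.

```{r example, eval = FALSE}
net <- build_network(default_config(pool_size = 100), seed = 1)
sim <- run_motor_task(net, "eat", seed = 1)
sim$activations
plot(sim)
```
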
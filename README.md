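# chainsim

Spiking-network simulations of **goal-directed neuronal chains** in the
inferior parietal lobule (IPL).  IPL neurons code elementary motor acts
(reaching, shaping, grasping, bringing to the mouth, placing), and many of
them — including parietal mirror neurons — fire differently for the *same*
act depending on the final goal of the sequence it belongs to (grasp to
eat vs. grasp to place).  `chainsim` implements the chain model of this
phenomenon: each action goal owns a dedicated unidirectional sequence of
neuronal pools, and executing or recognizing an action is the propagation
of an activity burst along that chain, gated by prefrontal intention
signals, sensory feedback and motor corollary discharge.

The package is aimed at computational neuroscientists who want to
reproduce, probe, or extend the chain mechanism: every parameter of the
neuron, synapse, topology, stimulus and plasticity model is exposed in one
configuration object, and every simulation is a pure function of
(configuration, seed).

## The model in brief

* **Neurons** — conductance-based leaky integrate-and-fire,
  `C_m dV/dt = -g_L (V - V_L) + I_syn`, threshold/reset with a 2 ms
  refractory period, advanced by first-order Euler steps (`dt = 0.1` ms).
* **Synapses** — kinetic AMPA, NMDA and GABA_A receptor channels,
  `I_X = -g_X (V - E_X) Σ_j w_j s_j`, with first-order gating
  `ds/dt = α[T](1-s) - βs` and the Jahr–Stevens magnesium unblock
  `B(V) = 1 / (1 + ([Mg]/3.57) e^(-0.062 V))` on NMDA.
* **Topology** — local pools (500 neurons, 25% inhibitory, exact 20%
  fan-in) linked by forward-only excitatory connections into goal-specific
  chains; two chains never share neurons even when they share motor acts.
* **Gating** — input from the previous pool alone is subthreshold; a pool
  ignites (avalanche) only when chain input coincides with sensory or
  observation input.  The visual task closes an inhibitory gate after
  premotor cortex, so recognition produces no motor output.
* **Plasticity** — STDP, `Δw = η E_j(t) K(t_post - t_pre)` with
  `K(Δt) = ±A_± exp(∓Δt/τ_±)`, `A_± = 1`, plus an activity-dependent
  efficacy `E` that is depressed at every presynaptic spike and recovers
  with `τ_E`.  Training an all-to-all four-pool network with overlapping
  template bursts hardwires it into a feedforward chain.

## Worked example

```r
library(chainsim)

net <- build_network(default_config(pool_size = 100), seed = 1)
net
#> <chain_network> 400 neurons, 4 pools, 1 chain(s)
#>   pools: eat.reaching, eat.shaping, eat.grasping, eat.bringing
#>   edges: local E 5978, local I 2022, inter 2400

sim <- run_motor_task(net, "eat", seed = 1)
sim
#> <chain_sim_result> 18470 spikes, 4 pools, 4 burst(s)
#>   activations: eat.reaching@40 ms, eat.shaping@280 ms,
#>                eat.grasping@520 ms, eat.bringing@780 ms
#>   completed: eat | halted:

sim$bursts
#>           pool onset offset  peak duration
#> 1 eat.reaching    40    360 180.5      320
#> 2  eat.shaping   280    580 203.0      300
#> 3 eat.grasping   520    820 146.0      300
#> 4 eat.bringing   760   1060 127.5      300
```

The four pools burst strictly in chain order, ~240 ms apart: the
prefrontal intention burst ignites `reaching` at t = 0; each activated
pool is sustained by corollary discharge for the 300 ms act duration, and
sensory feedback delivered toward act completion ignites the next pool
(chain input alone cannot — run with `sensory_enabled = FALSE` and the
chain halts after `reaching`).  `run_ambiguous_task()` starts the eat and
place chains in parallel and lets a late cue select the survivor;
`run_visual_task()` runs the same chains in recognition mode (no motor
events; a mid-action goal switch halts propagation at the mismatched
act).  `plot(sim)` draws the raster and the pool rate traces.

The template activity profiles used by the learning experiment reproduce
the in-vivo burst geometry exactly:

```r
tp <- gen_template_profiles()
measure_burst_stats(tp$rates, bin = 20, time = tp$time)
#> $bursts   — four bursts, width_ms = 300 (at half maximum)
#> $overlaps — successive-burst overlaps, overlap_ms = 80
```

and `run_learning_experiment()` trains the all-to-all network with them,
probing the chain at checkpoints (forward weights grow, backward weights
collapse; shuffled templates are the flat control).

A command-line front end with the same functionality is installed at
`inst/cli/chainsim` (subcommands `simulate-motor`, `simulate-blind`,
`simulate-visual`, `calibrate`, `learn-chain`).

See `vignettes/action-chains.Rmd` for the full model description,
parameter table, calibration rationale and limitations.

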
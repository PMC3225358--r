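test_that("magnesium block follows the Jahr-Stevens voltage dependence", {
  expect_equal(mg_block(0, Mg = 1), 1 / (1 + (1 / 3.57)), tolerance = 1e-12)
  expect_equal(mg_block(0, Mg = 1), 0.781, tolerance = 1e-3)
  expect_equal(mg_block(-70, Mg = 1), 1 / (1 + (1 / 3.57) * exp(0.062 * 70)),
               tolerance = 1e-12)
  expect_equal(mg_block(-70, Mg = 1), 0.0445, tolerance = 1e-2)
  # no magnesium, no block, at any potential
  expect_equal(mg_block(c(-90, -20, 40), Mg = 0), rep(1, 3))
  expect_error(mg_block(0, Mg = -1), "non-negative")
})

test_that("magnesium block is monotone in V and in 1/Mg and saturates", {
  V <- seq(-90, 60, by = 1)
  expect_true(all(diff(mg_block(V, Mg = 1)) > 0))
  Mg <- c(0, 0.5, 1, 2, 5)
  b <- mg_block(-55, Mg = Mg)
  expect_true(all(diff(b) < 0))
  expect_lt(abs(mg_block(500, Mg = 1) - 1), 1e-10)
})

test_that("receptor gating integrates its first-order kinetics", {
  # no drive, no opening
  expect_equal(update_gating(0, 0, 1.1, 0.19, 0.1), 0)
  # exponential decay oracle: s(t) = s0 exp(-beta t)
  s <- 1
  for (k in 1:2000) s <- update_gating(s, 0, 1.1, 0.19, 0.05)
  expect_equal(s, gating_decay(1, 0.19, 100), tolerance = 1e-2)
  # fixed point under sustained transmitter: alpha T / (alpha T + beta)
  s <- 0
  for (k in 1:4000) s <- update_gating(s, 1, 1.1, 0.19, 0.05)
  expect_equal(s, gating_fixed_point(1.1, 1, 0.19), tolerance = 1e-4)
  expect_equal(gating_fixed_point(1.1, 1, 0.19), 0.853, tolerance = 1e-3)
})

test_that("gating stays in [0,1] for random inputs and step sizes", {
  set.seed(42)
  for (rep in 1:200) {
    s <- runif(1)
    alpha <- runif(1, 0.01, 10); beta <- runif(1, 0.01, 1)
    dt <- runif(1, 0.01, 2); T_conc <- sample(c(0, 1), 1)
    for (k in 1:50) {
      s <- update_gating(s, T_conc, alpha, beta, dt)
      expect_gte(s, 0); expect_lte(s, 1)
    }
  }
})

test_that("receptor currents follow I = -g (V - E) sum(w s), NMDA Mg-blocked", {
  ampa <- receptor_params("AMPA_rec", g_max = 2, E_rev = 0,
                          alpha = 1.1, beta = 0.19)
  # silent afferents and reversal potential both give zero current
  expect_equal(receptor_current(c(0, 0), c(1, 1), -60, ampa), 0)
  expect_equal(receptor_current(0.7, 1, 0, ampa), 0)
  # single afferent: w = 1, s = 0.5, g = 2 nS, V - E = -60 mV -> +60 pA
  expect_equal(receptor_current(0.5, 1, -60, ampa), 60)
  # NMDA current additionally carries the unblock factor
  nmda <- receptor_params("NMDA", g_max = 2, E_rev = 0,
                          alpha = 0.072, beta = 0.0066, Mg = 1)
  expect_equal(receptor_current(0.5, 1, -60, nmda), 60 * mg_block(-60, 1))
  # inhibitory current is hyperpolarizing above its reversal
  gaba <- receptor_params("GABA", g_max = 1, E_rev = -70,
                          alpha = 5, beta = 0.18)
  expect_lt(receptor_current(0.5, 1, -55, gaba), 0)
  expect_error(receptor_current(c(0.1, 0.2), 1, -60, ampa), "length")
})

test_that("membrane step honors equilibrium, decay, threshold and refractoriness", {
  np <- neuron_params()
  st <- list(V = np$V_L, refr_remaining = 0)
  out <- step_membrane(st, np, 0, 0.1)
  expect_equal(out$state$V, np$V_L)
  expect_false(out$spiked)

  # passive decay oracle: V(t) = V_L + (V0 - V_L) exp(-t / tau_m)
  st <- list(V = -60, refr_remaining = 0)
  for (k in 1:200) st <- step_membrane(st, np, 0, 0.1)$state
  expect_equal(st$V, passive_decay(-60, -70, 20, 20), tolerance = 1e-3)
  expect_equal(passive_decay(-60, -70, 20, 20), -66.32, tolerance = 1e-3)

  # threshold rule: spike, reset, refractory clamp
  st <- list(V = np$V_thr - 0.01, refr_remaining = 0)
  out <- step_membrane(st, np, 5000, 0.1)
  expect_true(out$spiked)
  expect_equal(out$state$V, np$V_reset)
  expect_equal(out$state$refr_remaining, np$tau_ref)
  out2 <- step_membrane(out$state, np, 5000, 0.1)
  expect_false(out2$spiked)
  expect_equal(out2$state$V, np$V_reset)

  expect_error(step_membrane(st, np, NaN, 0.1), "non-finite")
})

test_that("Euler error shrinks ~10x when the step shrinks 10x", {
  np <- neuron_params()
  run_V <- function(dt) {
    st <- list(V = -60, refr_remaining = 0)
    for (k in seq_len(round(20 / dt))) st <- step_membrane(st, np, 0, dt)$state
    st$V
  }
  exact <- passive_decay(-60, -70, 20, 20)
  e1 <- abs(run_V(0.1) - exact)
  e2 <- abs(run_V(0.01) - exact)
  expect_lt(e2, e1 / 5)  # first-order convergence

  run_s <- function(dt) {
    s <- 0.9
    for (k in seq_len(round(10 / dt))) s <- update_gating(s, 0, 1.1, 0.19, dt)
    s
  }
  exact_s <- gating_decay(0.9, 0.19, 10)
  es1 <- abs(run_s(0.1) - exact_s)
  es2 <- abs(run_s(0.01) - exact_s)
  expect_lt(es2, es1 / 5)
})

test_that("parameter constructors validate their invariants", {
  expect_error(neuron_params(V_reset = -40, V_thr = -50), "V_reset")
  expect_error(neuron_params(C_m = 0), "positive")
  expect_error(receptor_params("AMPA_rec", g_max = -1, E_rev = 0,
                               alpha = 1, beta = 1), "non-negative")
  expect_error(receptor_params("NMDA", g_max = 1, E_rev = 0,
                               alpha = 1, beta = 1, Mg = -2), "magnesium")
  expect_equal(neuron_params()$tau_m, 20)
})
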
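test_that("the C++ integrator matches the R reference neuron exactly", {
  cfg <- test_config()
  set.seed(31)
  ext <- sort(runif(120, 5, 280))  # ~430 Hz drive, enough to spike
  rr <- r_reference_neuron(ext, 300, cfg)
  cc <- cpp_reference_neuron(ext, 300, cfg)
  expect_gt(length(rr$spikes), 3)  # the scenario actually fires
  expect_equal(cc$spikes, rr$spikes, tolerance = 1e-9)
  expect_equal(cc$V, rr$V[length(rr$V)], tolerance = 1e-9)
})

test_that("burst detection reports half-maximum intervals above the floor", {
  expect_equal(nrow(detect_pool_activation(rep(0, 50))), 0)
  expect_equal(nrow(detect_pool_activation(rep(10, 50), floor = 20)), 0)
  # single synthetic Gaussian bump: one burst, half-maximum width
  tt <- seq(10, 990, by = 20)
  bump <- 100 * exp(-(tt - 500)^2 / (2 * 80^2))
  d <- detect_pool_activation(bump, bin = 20, floor = 20)
  expect_equal(nrow(d), 1)
  fwhm <- 2 * sqrt(2 * log(2)) * 80
  expect_lt(abs(d$duration - fwhm), 25)
  expect_equal(d$peak, max(bump))
  # two disjoint bumps in order
  two <- 100 * exp(-(tt - 300)^2 / (2 * 50^2)) +
         90 * exp(-(tt - 750)^2 / (2 * 50^2))
  d2 <- detect_pool_activation(two, bin = 20, floor = 20)
  expect_equal(nrow(d2), 2)
  expect_lt(d2$onset[1], d2$onset[2])
})

test_that("motor task: bursts follow chain order and need sensory gating", {
  net <- build_network(test_config(), seed = 6)
  sim <- run_motor_task(net, "eat", seed = 6)
  act <- sim$activations
  expect_true(all(!is.na(act)))
  expect_true(all(diff(unname(act)) > 0))  # strictly increasing onsets
  expect_equal(sim$outcome$completed_chains, "eat")
  # every pool bursts
  expect_setequal(unique(sim$bursts$pool), net$pools$pool)
  # refractory contract on the raster
  isi_ok <- tapply(sim$raster$t, sim$raster$neuron, function(t)
    length(t) < 2 || min(diff(sort(t))) >= net$config$neuron$tau_ref - 1e-9)
  expect_true(all(unlist(isi_ok)))
  # without sensory feedback the chain halts after the first pool
  halted <- run_motor_task(net, "eat", seed = 6, sensory_enabled = FALSE)
  expect_equal(sum(!is.na(halted$activations)), 1)
  expect_equal(halted$outcome$halted_chains, "eat")
})

test_that("stretching the act duration stretches propagation, same order", {
  net <- build_network(test_config(), seed = 8)
  s1 <- run_motor_task(net, "eat", act_duration = 300, seed = 8)
  s2 <- run_motor_task(net, "eat", act_duration = 600, seed = 8,
                       duration = 3500)
  a1 <- unname(s1$activations); a2 <- unname(s2$activations)
  expect_true(all(!is.na(a1)) && all(!is.na(a2)))
  expect_true(all(diff(a2) > 0))
  # inter-burst intervals roughly double
  expect_gt(mean(diff(a2)) / mean(diff(a1)), 1.6)
  # same number of bursts per pool
  expect_equal(sum(!is.na(a2)), sum(!is.na(a1)))
})

test_that("ambiguous task: parallel start, cue-selected completion", {
  two <- list(eat = c("reaching", "shaping", "grasping", "bringing"),
              place = c("reaching", "shaping", "grasping", "placing"))
  net <- build_network(test_config(), chains = two, seed = 9)
  sim <- run_ambiguous_task(net, cue = "eat", seed = 9)
  a <- sim$activations
  shared <- c("reaching", "shaping", "grasping")
  expect_true(all(!is.na(a[paste0("eat.", shared)])))
  expect_true(all(!is.na(a[paste0("place.", shared)])))
  expect_false(is.na(a[["eat.bringing"]]))
  expect_true(is.na(a[["place.placing"]]))
  expect_true("eat" %in% sim$outcome$completed_chains)
  expect_true("place" %in% sim$outcome$halted_chains)
  # label symmetry: cueing the other goal swaps the roles
  sim2 <- run_ambiguous_task(net, cue = "place", seed = 9)
  expect_false(is.na(sim2$activations[["place.placing"]]))
  expect_true(is.na(sim2$activations[["eat.bringing"]]))
})

test_that("visual task: recognition without motor output, halts on mismatch", {
  net <- build_network(test_config(), seed = 10)
  sim <- run_visual_task(net, "eat", seed = 10)
  expect_true(all(!is.na(sim$activations)))
  expect_length(sim$motor_events, 0)
  expect_gt(length(sim$suppressed_motor), 0)
  # goal switch mid-action: propagation stops at the mismatched act
  mis <- run_visual_task(net, "eat",
                         observed = c("reaching", "shaping", "lifting",
                                      "throwing"), seed = 10)
  expect_equal(sum(!is.na(mis$activations)), 2)
  expect_length(mis$motor_events, 0)
  downstream <- c("eat.grasping", "eat.bringing")
  expect_true(all(!downstream %in% mis$bursts$pool))
  # prediction input alone never ignites anything
  pred <- run_visual_task(net, "eat", observed = character(0),
                          duration = 1000, seed = 10)
  expect_equal(nrow(pred$bursts), 0)
})

test_that("simulation results are reproducible and carry a manifest", {
  net <- one_pool_net(seed = 2)
  b <- gen_intention_burst(net, "p.act", seed = 2)
  s1 <- simulate_network(net, list(b), duration = 400, seed = 2)
  s2 <- simulate_network(net, list(b), duration = 400, seed = 2)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$pool_rates, s2$pool_rates)
  expect_equal(s1$manifest$seed, 2)
  expect_match(s1$manifest$config_hash, "^[0-9a-f]+$")
})

test_that("Eq-1 style current decomposition is reported per source", {
  net <- build_network(test_config(), seed = 12)
  sim <- run_motor_task(net, "eat", seed = 12, record_currents = TRUE)
  expect_length(sim$currents, nrow(sim$pool_rates))
  cur <- sim$currents[[10]]
  expect_equal(dim(cur), c(4, 7))  # prev, localE, localI, 4 ext channels
  # during the intention burst the first pool receives PFC current
  early <- Reduce(`+`, sim$currents[1:8])
  expect_gt(early[1, 4], 0)    # pfc onto reaching: depolarizing
  expect_lt(early[1, 3], 1e-9) # local inhibition is hyperpolarizing (or 0)
})
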
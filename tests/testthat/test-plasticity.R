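test_that("the STDP kernel has the printed shape and maximum", {
  p <- stdp_params()
  expect_equal(stdp_kernel(20, p), exp(-1))
  expect_equal(stdp_kernel(-20, p), -exp(-1))
  expect_equal(stdp_kernel(0, p), 0)
  # vanishes at long lags
  expect_lt(abs(stdp_kernel(1e4, p)), 1e-100)
  expect_lt(abs(stdp_kernel(-1e4, p)), 1e-100)
  # maximum absolute modification is 1 with the default amplitudes
  grid <- seq(-500, 500, by = 0.01)
  expect_equal(max(abs(stdp_kernel(grid, p))), 1, tolerance = 1e-3)
  # sign antisymmetry
  dts <- c(-80, -35, -5, 5, 35, 80)
  expect_equal(sign(stdp_kernel(dts, p)), -sign(stdp_kernel(-dts, p)))
})

test_that("synaptic efficacy depresses per spike and recovers exponentially", {
  p <- stdp_params(u = 0.2, tau_E = 500)
  expect_equal(update_efficacy(1, TRUE, 0.1, p), 0.8)
  # closed-form recovery oracle
  E <- 0.5
  for (k in 1:2000) E <- update_efficacy(E, FALSE, 0.05, p)
  expect_equal(E, efficacy_recovery(0.5, 500, 100), tolerance = 1e-3)
  # rapid spiking drives E monotonically toward a depressed floor
  E <- 1; prev <- 1
  for (k in 1:50) {
    E <- update_efficacy(E, TRUE, 0.1, p)
    expect_lt(E, prev); prev <- E
    expect_gt(E, 0)
  }
  expect_lt(E, 0.01)
})

test_that("weight updates follow eta * E * kernel with bounds", {
  n <- 2
  W <- Matrix::sparseMatrix(i = 2, j = 1, x = 0.5, dims = c(n, n))
  p <- stdp_params(eta = 0.01, tau_plus = 20, u = 0, pairing = "nearest")
  # eta = 0 leaves weights unchanged
  sp <- data.frame(t = c(10, 20), neuron = c(1L, 2L))
  W0 <- apply_weight_update(W, sp, n, stdp_params(eta = 0))
  expect_equal(W0[2, 1], 0.5)
  # single pre-post pair at +10 ms, full efficacy: dw = 0.01 * exp(-0.5)
  W1 <- apply_weight_update(W, sp, n, p)
  expect_equal(W1[2, 1], 0.5 + 0.01 * exp(-10 / 20), tolerance = 1e-12)
  expect_equal(0.01 * exp(-0.5), 0.00607, tolerance = 1e-3)
  # with short-term depression the pre neuron's efficacy scales the update
  pE <- stdp_params(eta = 0.01, tau_plus = 20, u = 0.2, tau_E = 500)
  WE <- apply_weight_update(W, sp, n, pE)
  E_pre <- 1 - 0.2 * exp(-10 / 500)  # depressed at t=10, recovered to t=20
  expect_equal(WE[2, 1], 0.5 + 0.01 * E_pre * exp(-0.5), tolerance = 1e-12)
  # post-then-pre ordering weakens the synapse
  sp2 <- data.frame(t = c(10, 20), neuron = c(2L, 1L))
  W2 <- apply_weight_update(W, sp2, n, p)
  expect_lt(W2[2, 1], 0.5)
  # bounds respected under dense spiking
  dense <- data.frame(t = sort(runif(2000, 0, 500)),
                      neuron = sample(1:2, 2000, replace = TRUE))
  W3 <- apply_weight_update(W, dense, n, stdp_params(eta = 0.5, w_max = 2))
  expect_gte(W3[2, 1], 0)
  expect_lte(W3[2, 1], 2)
  expect_false(any(!is.finite(W3@x)))
})

test_that("event-driven all-pairs STDP matches the brute-force double loop", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 6
    edges <- expand.grid(pre = 1:n, post = 1:n)
    edges <- edges[edges$pre != edges$post, ]
    edges <- edges[sample(nrow(edges), 18), ]
    edges$w <- runif(nrow(edges), 0.5, 1.5)
    spikes <- data.frame(t = sort(runif(50, 0, 400)),
                         neuron = sample(1:n, 50, replace = TRUE))
    par <- stdp_params(eta = 0.05, tau_plus = 17, tau_minus = 23,
                       tau_E = 300, u = 0.15, w_min = 0, w_max = 100,
                       pairing = "all")
    W <- Matrix::sparseMatrix(i = edges$post, j = edges$pre, x = edges$w,
                              dims = c(n, n))
    Wev <- apply_weight_update(W, spikes, n, par)
    # brute force needs the same edge enumeration as the sparse matrix
    s <- Matrix::summary(methods::as(W, "CsparseMatrix"))
    ed <- data.frame(pre = s$j, post = s$i, w = s$x)
    wbf <- brute_stdp(ed, spikes, par)
    expect_equal(Wev[cbind(ed$post, ed$pre)], wbf, tolerance = 1e-10)
  }
})

test_that("nearest-spike pairing bounds the update per spike", {
  n <- 2
  W <- Matrix::sparseMatrix(i = 2, j = 1, x = 1, dims = c(n, n))
  # pre fires a long regular burst, then one post spike: under all-pairs the
  # potentiation sums over the whole burst, under nearest only the last
  pre_t <- seq(1, 96, by = 5)
  sp <- data.frame(t = c(pre_t, 100), neuron = c(rep(1L, length(pre_t)), 2L))
  par_n <- stdp_params(eta = 1, u = 0, pairing = "nearest", w_max = 100)
  par_a <- stdp_params(eta = 1, u = 0, pairing = "all", w_max = 100)
  dn <- apply_weight_update(W, sp, n, par_n)[2, 1] - 1
  da <- apply_weight_update(W, sp, n, par_a)[2, 1] - 1
  expect_equal(dn, exp(-4 / 20), tolerance = 1e-12)
  expect_equal(da, sum(exp(-(100 - pre_t) / 20)), tolerance = 1e-12)
  expect_gt(da, dn)
})

test_that("chain learning hardwires a feedforward chain, controls do not", {
  cfg <- test_config()
  lr <- run_learning_experiment(cfg, sessions = 60,
                                checkpoints = c(0, 30, 60), seed = 3)
  wt <- lr$weight_trace
  fin <- wt[wt$checkpoint == 60, ]
  expect_true(all(fin$forward > fin$backward))
  # forward weights grow across checkpoints
  fw <- tapply(wt$forward, wt$checkpoint, mean)
  expect_true(all(diff(fw) > 0))
  # probed first pool always responds; response is recorded per checkpoint
  expect_true(all(lr$probe_peaks[, 1] > 50))
  expect_equal(dim(lr$probe_peaks), c(3, 4))
  # shuffled-template control: no consistent forward/backward asymmetry
  ctl <- run_learning_experiment(cfg, sessions = 60, checkpoints = 60,
                                 seed = 3, shuffle = TRUE)
  cf <- ctl$weight_trace[ctl$weight_trace$checkpoint == 60, ]
  expect_lt(mean(cf$forward - cf$backward),
            0.5 * mean(fin$forward - fin$backward))
})
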
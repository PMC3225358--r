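test_that("pool construction enforces exact counts", {
  p <- build_pool(500, inh_fraction = 0.25, p_intra = 0.20,
                  w_E = 1, w_I = 2, seed = 7)
  expect_equal(sum(p$inhibitory), 125)
  fan_in <- Matrix::rowSums(p$W_E != 0) + Matrix::rowSums(p$W_I != 0)
  expect_true(all(fan_in == 100))
  # excitatory / inhibitory partners carry their respective weights
  expect_true(all(p$W_E@x == 1))
  expect_true(all(p$W_I@x == 2))
  # no self-connections
  expect_equal(sum(Matrix::diag(p$W_E)) + sum(Matrix::diag(p$W_I)), 0)
  # presynaptic columns match the inhibitory mask
  used_I <- unique(Matrix::summary(p$W_I)$j)
  expect_true(all(p$inhibitory[used_I]))

  empty <- build_pool(50, p_intra = 0, seed = 1)
  expect_equal(length(empty$W_E@x), 0)
  expect_error(build_pool(1), "at least 2")
})

test_that("chains are strictly feedforward and exclusively excitatory", {
  cfg <- test_config()
  net <- build_network(cfg, seed = 3)
  W <- net$W_inter
  s <- Matrix::summary(W)
  pool_of <- function(i) findInterval(i, net$pools$from)
  # 4-pool chain: exactly 3 forward blocks, no backward entries
  expect_true(all(pool_of(s$i) == pool_of(s$j) + 1))
  # inhibitory neurons have no outgoing inter-pool entries
  expect_false(any(net$inhibitory[s$j]))
  # degree-regular chain fan-in
  fan_in <- table(factor(s$i, levels = pool_neurons(net, "eat.shaping")))
  expect_true(all(fan_in == round(0.10 * 75)))
  # duplicate / repeated pools rejected
  expect_error(connect_chain(net$pools, net$inhibitory,
                             c("eat.reaching", "eat.reaching"), 1),
               "twice|once")
})

test_that("network construction is deterministic and chains are disjoint", {
  cfg <- test_config()
  two <- list(eat = c("reaching", "shaping", "grasping", "bringing"),
              place = c("reaching", "shaping", "grasping", "placing"))
  a <- build_network(cfg, chains = two, seed = 11)
  b <- build_network(cfg, chains = two, seed = 11)
  expect_identical(rlang::hash(Matrix::summary(a$W_local_E)),
                   rlang::hash(Matrix::summary(b$W_local_E)))
  expect_identical(rlang::hash(Matrix::summary(a$W_inter)),
                   rlang::hash(Matrix::summary(b$W_inter)))
  expect_identical(a$inhibitory, b$inhibitory)
  # different seed: same degree counts, different placement
  d <- build_network(cfg, chains = two, seed = 12)
  deg <- function(net) Matrix::rowSums(net$W_local_E != 0) +
    Matrix::rowSums(net$W_local_I != 0)
  expect_equal(unname(deg(d)), unname(deg(a)))
  expect_equal(sum(d$inhibitory), sum(a$inhibitory))
  expect_equal(length(d$W_inter@x), length(a$W_inter@x))
  expect_false(identical(Matrix::summary(a$W_local_E),
                         Matrix::summary(d$W_local_E)))
  # the two chains share no neurons even for shared motor acts
  eat_ids <- unlist(lapply(paste0("eat.", two$eat), pool_neurons, network = a))
  place_ids <- unlist(lapply(paste0("place.", two$place), pool_neurons,
                             network = a))
  expect_length(intersect(eat_ids, place_ids), 0)
  # 8 pools of 100 -> 800 neurons
  expect_equal(a$n, 800)
})

test_that("inhibitory out-edges never cross pool boundaries", {
  net <- build_network(test_config(), seed = 5)
  for (W in list(net$W_local_E, net$W_local_I)) {
    s <- Matrix::summary(W)
    pool_pre <- findInterval(s$j, net$pools$from)
    pool_post <- findInterval(s$i, net$pools$from)
    expect_true(all(pool_pre == pool_post))
  }
})

test_that("the learning network is all-to-all between pools with low weights", {
  cfg <- test_config()
  net <- build_learning_network(cfg, seed = 4)
  s <- Matrix::summary(net$W_inter)
  pool_of <- findInterval(s$j, net$pools$from)
  pool_to <- findInterval(s$i, net$pools$from)
  # every ordered pool pair is connected (12 directed pairs for 4 pools)
  pairs <- unique(paste(pool_of, pool_to))
  expect_length(pairs, 12)
  expect_false(any(pool_of == pool_to))
  scale <- cfg$topology$reference_size / cfg$topology$pool_size
  expect_true(all(s$x >= cfg$plasticity$w_init[1] * scale - 1e-12))
  expect_true(all(s$x <= cfg$plasticity$w_init[2] * scale + 1e-12))
  expect_false(any(net$inhibitory[s$j]))
})

test_that("weight rescaling keeps per-neuron drive constant across pool sizes", {
  cfg_small <- default_config(pool_size = 100)
  cfg_big <- default_config(pool_size = 500)
  net_s <- build_network(cfg_small, chains = list(p = "act"), seed = 1)
  net_b <- build_network(cfg_big, chains = list(p = "act"), seed = 1)
  drive_s <- Matrix::rowSums(net_s$W_local_E)[1]
  drive_b <- Matrix::rowSums(net_b$W_local_E)[1]
  expect_equal(sum(Matrix::rowSums(net_s$W_local_E)) / net_s$n,
               sum(Matrix::rowSums(net_b$W_local_E)) / net_b$n,
               tolerance = 0.05)
})
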
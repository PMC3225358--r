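#' Build one local pool
#'
#' Constructs the local wiring of a pool: `round(inh_fraction * size)`
#' neurons are randomly chosen to be inhibitory, and every neuron receives
#' connections from exactly `round(p_intra * size)` distinct in-pool
#' partners (exact fan-in, sampled without replacement, no
#' self-connections).  Excitatory partners project with weight `w_E`
#' (recurrent AMPA + NMDA), inhibitory partners with `w_I` (GABA).
#'
#' @param size number of neurons (>= 2).
#' @param inh_fraction fraction of inhibitory neurons.
#' @param p_intra intra-pool connection fraction; fan-in is
#'   `round(p_intra * size)` per neuron.
#' @param w_E,w_I local excitatory / inhibitory weights (dimensionless).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return list with `inhibitory` (logical vector) and sparse weight
#'   matrices `W_E`, `W_I` (`size x size`, rows = postsynaptic,
#'   columns = presynaptic).
#' @export
build_pool <- function(size, inh_fraction = 0.25, p_intra = 0.20,
                       w_E = 1, w_I = 1, seed = NULL) {
  if (size < 2) stop("pool size must be at least 2", call. = FALSE)
  stopifnot(inh_fraction >= 0, inh_fraction <= 1, p_intra >= 0, p_intra <= 1)
  with_seed_(seed, {
    n_inh <- round(inh_fraction * size)
    inhibitory <- rep(FALSE, size)
    inhibitory[sample.int(size, n_inh)] <- TRUE
    fan_in <- round(p_intra * size)
    if (fan_in > size - 1) fan_in <- size - 1
    if (fan_in > 0) {
      pre <- unlist(lapply(seq_len(size), function(post)
        sample(setdiff(seq_len(size), post), fan_in)))
      post <- rep(seq_len(size), each = fan_in)
      exc <- !inhibitory[pre]
      W_E <- Matrix::sparseMatrix(i = post[exc], j = pre[exc],
                                  x = rep(w_E, sum(exc)), dims = c(size, size))
      W_I <- Matrix::sparseMatrix(i = post[!exc], j = pre[!exc],
                                  x = rep(w_I, sum(!exc)), dims = c(size, size))
    } else {
      W_E <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(size, size))
      W_I <- W_E
    }
    list(inhibitory = inhibitory,
         W_E = methods::as(W_E, "CsparseMatrix"),
         W_I = methods::as(W_I, "CsparseMatrix"))
  })
}

#' Wire the inter-pool links of one chain
#'
#' For each consecutive pool pair (k, k+1) of the chain, every neuron of
#' pool k+1 receives connections from exactly
#' `round(p_inter * n_exc_k)` randomly chosen *excitatory* neurons of
#' pool k, with weight `w_chain` (exact fan-in, mirroring the local
#' wiring scheme; a degree-regular graph keeps the subthreshold chain
#' input uniform across the target pool).  Links are strictly
#' unidirectional: no backward entries are created, and inhibitory
#' neurons never project outside their pool.
#'
#' @param pools pool table of a network (see [build_network()]): columns
#'   `pool` (id), `from`, `to` (neuron index range).
#' @param inhibitory global logical vector of inhibitory flags.
#' @param chain_pools character vector of pool ids in chain order.
#' @param w_chain inter-pool weight.
#' @param p_inter fraction of the target pool contacted by each source.
#' @param n total number of neurons in the network.
#' @param seed RNG seed.
#' @return sparse `n x n` weight matrix (rows = post, cols = pre) holding
#'   only this chain's forward inter-pool entries.
#' @export
connect_chain <- function(pools, inhibitory, chain_pools, w_chain,
                          p_inter = 0.10, n = max(pools$to), seed = NULL) {
  if (any(chain_pools[-1] == chain_pools[-length(chain_pools)]))
    stop("a pool appears twice consecutively in the chain", call. = FALSE)
  if (anyDuplicated(chain_pools))
    stop("pools must appear once per chain", call. = FALSE)
  idx <- match(chain_pools, pools$pool)
  if (anyNA(idx)) stop("unknown pool id in chain", call. = FALSE)
  with_seed_(seed, {
    ii <- integer(); jj <- integer()
    for (k in seq_len(length(idx) - 1L)) {
      a <- pools[idx[k], ]; b <- pools[idx[k + 1L], ]
      src <- seq.int(a$from, a$to)
      src <- src[!inhibitory[src]]
      tgt <- seq.int(b$from, b$to)
      fan_in <- round(p_inter * length(src))
      if (fan_in > 0) {
        for (tt in tgt) {
          s <- sample(src, fan_in)
          ii <- c(ii, rep.int(tt, fan_in)); jj <- c(jj, s)
        }
      }
    }
    methods::as(Matrix::sparseMatrix(i = ii, j = jj, x = rep(w_chain, length(ii)),
                                     dims = c(n, n)), "CsparseMatrix")
  })
}

pool_table_ <- function(specs, size) {
  n_pools <- length(specs)
  data.frame(
    pool = vapply(specs, `[[`, "", "pool"),
    motor_act = vapply(specs, `[[`, "", "motor_act"),
    chain = vapply(specs, function(s) s$chain %||% NA_character_, ""),
    from = (seq_len(n_pools) - 1L) * size + 1L,
    to = seq_len(n_pools) * size,
    size = size,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a chain-structured network
#'
#' Assembles pools and chains into a full network topology.  Each chain is
#' a named ordered sequence of motor acts and receives its own, physically
#' distinct pools even when two chains code the same act (e.g. the
#' grasp-to-eat and grasp-to-place chains both contain a "grasping" pool,
#' but these pools share no neurons).  Weights `w_E`, `w_I`, `w_chain`
#' from the configuration are rescaled by `reference_size / pool_size` so
#' that pool dynamics are comparable across pool sizes.
#'
#' @param config a [default_config()] list.
#' @param chains named list of character vectors of motor acts, e.g.
#'   `list(eat = c("reaching", "shaping", "grasping", "bringing"))`.
#' @param seed RNG seed; the construction is fully deterministic given
#'   the seed.
#' @return an object of class `chain_network`: pool table, chain list,
#'   inhibitory flags, and sparse matrices `W_local_E`, `W_local_I`,
#'   `W_inter` (rows = post, cols = pre).
#' @examples
#' net <- build_network(default_config(pool_size = 50),
#'                      chains = list(eat = c("reaching", "grasping")),
#'                      seed = 1)
#' net$pools
#' @export
build_network <- function(config = default_config(),
                          chains = list(eat = c("reaching", "shaping",
                                                "grasping", "bringing")),
                          seed = 1) {
  top <- config$topology
  specs <- list()
  for (cn in names(chains)) {
    for (act in chains[[cn]]) {
      specs[[length(specs) + 1L]] <-
        list(pool = paste(cn, act, sep = "."), motor_act = act, chain = cn)
    }
  }
  ids <- vapply(specs, `[[`, "", "pool")
  if (anyDuplicated(ids)) stop("duplicate pool ids", call. = FALSE)
  pools <- pool_table_(specs, top$pool_size)
  n <- max(pools$to)
  scale <- top$reference_size / top$pool_size
  w_E <- top$w_E * scale; w_I <- top$w_I * scale; w_chain <- top$w_chain * scale

  with_seed_(seed, {
    inhibitory <- logical(n)
    WE <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, n))
    WI <- WE
    for (p in seq_len(nrow(pools))) {
      loc <- build_pool(top$pool_size, top$inh_fraction, top$p_intra,
                        w_E, w_I, seed = NULL)
      rng <- seq.int(pools$from[p], pools$to[p])
      inhibitory[rng] <- loc$inhibitory
      trip_E <- Matrix::summary(loc$W_E); trip_I <- Matrix::summary(loc$W_I)
      if (nrow(trip_E))
        WE <- WE + Matrix::sparseMatrix(i = trip_E$i + pools$from[p] - 1L,
                                        j = trip_E$j + pools$from[p] - 1L,
                                        x = trip_E$x, dims = c(n, n))
      if (nrow(trip_I))
        WI <- WI + Matrix::sparseMatrix(i = trip_I$i + pools$from[p] - 1L,
                                        j = trip_I$j + pools$from[p] - 1L,
                                        x = trip_I$x, dims = c(n, n))
    }
    Wint <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(n, n))
    for (cn in names(chains)) {
      cp <- paste(cn, chains[[cn]], sep = ".")
      Wint <- Wint + connect_chain(pools, inhibitory, cp, w_chain,
                                   top$p_inter, n, seed = NULL)
    }
    structure(list(
      config = config, chains = chains, pools = pools, n = n,
      inhibitory = inhibitory,
      W_local_E = methods::as(WE, "CsparseMatrix"),
      W_local_I = methods::as(WI, "CsparseMatrix"),
      W_inter = methods::as(Wint, "CsparseMatrix"),
      seed = seed
    ), class = "chain_network")
  })
}

#' Build the all-to-all learning network
#'
#' Four (by default) pools, one per motor act, with standard local wiring
#' but inter-pool excitatory connections between *every* ordered pool pair
#' initialised to low random weights drawn uniformly from
#' `config$plasticity$w_init`.  This is the substrate of the chain
#' learning experiment: spike-timing-dependent plasticity later carves a
#' feedforward chain out of this unstructured connectivity.
#'
#' @param config a [default_config()] list.
#' @param acts motor act labels, one pool each.
#' @param seed RNG seed.
#' @return a `chain_network` with an additional `plastic_mask` attribute
#'   marking the inter-pool entries subject to plasticity.
#' @export
build_learning_network <- function(config = default_config(),
                                   acts = c("reaching", "shaping",
                                            "grasping", "bringing"),
                                   seed = 1) {
  top <- config$topology
  specs <- lapply(acts, function(a) list(pool = a, motor_act = a, chain = "learn"))
  pools <- pool_table_(specs, top$pool_size)
  n <- max(pools$to)
  scale <- top$reference_size / top$pool_size
  with_seed_(seed, {
    inhibitory <- logical(n)
    WE <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, n))
    WI <- WE
    for (p in seq_len(nrow(pools))) {
      loc <- build_pool(top$pool_size, top$inh_fraction, top$p_intra,
                        top$w_E * scale, top$w_I * scale, seed = NULL)
      rng <- seq.int(pools$from[p], pools$to[p])
      inhibitory[rng] <- loc$inhibitory
      trip_E <- Matrix::summary(loc$W_E); trip_I <- Matrix::summary(loc$W_I)
      if (nrow(trip_E))
        WE <- WE + Matrix::sparseMatrix(i = trip_E$i + pools$from[p] - 1L,
                                        j = trip_E$j + pools$from[p] - 1L,
                                        x = trip_E$x, dims = c(n, n))
      if (nrow(trip_I))
        WI <- WI + Matrix::sparseMatrix(i = trip_I$i + pools$from[p] - 1L,
                                        j = trip_I$j + pools$from[p] - 1L,
                                        x = trip_I$x, dims = c(n, n))
    }
    ii <- integer(); jj <- integer()
    for (a in seq_len(nrow(pools))) for (b in seq_len(nrow(pools))) {
      if (a == b) next
      src <- seq.int(pools$from[a], pools$to[a])
      src <- src[!inhibitory[src]]
      tgt <- seq.int(pools$from[b], pools$to[b])
      fan_in <- round(top$p_inter * length(src))
      for (tt in tgt) {
        s <- sample(src, fan_in)
        ii <- c(ii, rep.int(tt, fan_in)); jj <- c(jj, s)
      }
    }
    w0 <- runif(length(ii), config$plasticity$w_init[1], config$plasticity$w_init[2])
    Wint <- methods::as(Matrix::sparseMatrix(i = ii, j = jj, x = w0 * scale,
                                             dims = c(n, n)), "CsparseMatrix")
    structure(list(
      config = config, chains = list(learn = acts), pools = pools, n = n,
      inhibitory = inhibitory,
      W_local_E = methods::as(WE, "CsparseMatrix"),
      W_local_I = methods::as(WI, "CsparseMatrix"),
      W_inter = Wint,
      seed = seed
    ), class = "chain_network")
  })
}

#' @export
print.chain_network <- function(x, ...) {
  cat("<chain_network> ", x$n, " neurons, ", nrow(x$pools), " pools, ",
      length(x$chains), " chain(s)\n", sep = "")
  cat("  pools: ", paste(x$pools$pool, collapse = ", "), "\n", sep = "")
  cat("  edges: local E ", length(x$W_local_E@x),
      ", local I ", length(x$W_local_I@x),
      ", inter ", length(x$W_inter@x), "\n", sep = "")
  invisible(x)
}

#' Neuron index range of a pool
#' @param network a `chain_network`.
#' @param pool pool id (e.g. `"eat.grasping"`).
#' @param type `"all"` or `"excitatory"` (external afferents contact the
#'   pyramidal neurons; pool interneurons are recruited through the
#'   recurrent collaterals).
#' @return integer vector of neuron indices.
#' @export
pool_neurons <- function(network, pool, type = c("all", "excitatory")) {
  type <- match.arg(type)
  p <- match(pool, network$pools$pool)
  if (is.na(p)) stop("unknown pool: ", pool, call. = FALSE)
  ids <- seq.int(network$pools$from[p], network$pools$to[p])
  if (type == "excitatory") ids <- ids[!network$inhibitory[ids]]
  ids
}

#' Serialize a network's sparse weights to CSV
#'
#' Writes the weight structure as triplets
#' `(pre_id, post_id, weight, receptor_kind)` with
#' `receptor_kind` one of `local_E`, `local_I`, `inter`, plus a sidecar
#' JSON manifest (seed, config hash, pool table).  `read_topology()`
#' inverts the write.
#'
#' @param network a `chain_network`.
#' @param path output CSV path (manifest written next to it as
#'   `<path>.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_topology <- function(network, path) {
  tr <- function(W, kind) {
    s <- Matrix::summary(W)
    if (!nrow(s)) return(NULL)
    data.frame(pre_id = s$j, post_id = s$i, weight = s$x, receptor_kind = kind)
  }
  df <- rbind(tr(network$W_local_E, "local_E"),
              tr(network$W_local_I, "local_I"),
              tr(network$W_inter, "inter"))
  utils::write.csv(df, path, row.names = FALSE)
  man <- list(seed = network$seed, n = network$n,
              config_hash = config_hash(network$config),
              pools = network$pools, chains = network$chains,
              inhibitory = which(network$inhibitory))
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
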
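# Rasters, PSTHs, burst metrics and result (de)serialization.

#' Peri-stimulus time histogram of a spike raster
#'
#' Bins spikes relative to an alignment time (half-open bins
#' `[t, t + bin)`) and converts counts to a population rate in Hz,
#' `rate = counts / (n_neurons * bin)`.  When the raster carries a `pool`
#' column one histogram per pool is returned.
#'
#' @param raster data.frame with columns `t` (ms) and optionally `pool`
#'   and `neuron`.
#' @param bin_width bin, ms (default 20).
#' @param alignment_time event the histogram is aligned to, ms; bin 0
#'   starts there.
#' @param n_neurons neurons contributing per pool (scalar or named by
#'   pool); required to scale counts to Hz.
#' @param t_range time range (relative to alignment) to cover, ms;
#'   defaults to the span of the data.
#' @return list of class `psth`: `time` (bin starts, ms, relative),
#'   `counts` and `rate` (matrices, one column per pool), `bin_width`.
#' @export
compute_psth <- function(raster, bin_width = 20, alignment_time = 0,
                         n_neurons = 1, t_range = NULL) {
  stopifnot(bin_width > 0)
  t_rel <- raster$t - alignment_time
  explicit <- !is.null(t_range)
  if (!explicit)
    t_range <- if (nrow(raster)) range(t_rel) else c(0, bin_width)
  lo <- floor(t_range[1] / bin_width) * bin_width
  hi <- if (explicit) {
    # half-open window [t0, t1): the upper edge lands on t1 when aligned
    lo + bin_width * max(1, ceiling((t_range[2] - lo) / bin_width - 1e-9))
  } else {
    floor(t_range[2] / bin_width) * bin_width + bin_width
  }
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  pools <- if ("pool" %in% names(raster) && nrow(raster))
    sort(unique(as.character(raster$pool))) else "all"
  counts <- matrix(0L, nb, length(pools), dimnames = list(NULL, pools))
  if (nrow(raster)) {
    pb <- if ("pool" %in% names(raster)) as.character(raster$pool)
          else rep("all", nrow(raster))
    ib <- floor((t_rel - lo) / bin_width) + 1L
    ok <- ib >= 1L & ib <= nb
    for (p in pools) {
      sel <- ok & pb == p
      counts[, p] <- tabulate(ib[sel], nb)
    }
  }
  nn <- if (length(n_neurons) == 1L) rep(n_neurons, length(pools))
        else n_neurons[pools]
  rate <- sweep(counts, 2, unlist(nn) * bin_width / 1000, "/")
  structure(list(time = edges[-length(edges)], counts = counts, rate = rate,
                 bin_width = bin_width, alignment_time = alignment_time),
            class = "psth")
}

#' Burst statistics of binned rate profiles
#'
#' For each profile (column), measures the burst at half maximum on the
#' PSTH bin grid: onset, peak, and half-maximum width; plus, for each
#' consecutive pair of profiles, the time both are simultaneously above
#' their respective half-maxima.  Widths and overlaps are reported in ms
#' as multiples of the bin width.
#'
#' @param rates matrix of rates (rows = time, one column per profile) or a
#'   `psth` object.  If `rates` is sampled finer than `bin` (a `time`
#'   vector must then be supplied), it is first averaged down to `bin`.
#' @param bin analysis bin width, ms.
#' @param time sample times of `rates` rows, ms (needed when `rates` is
#'   not already binned at `bin`).
#' @return list with `bursts` (data.frame: profile, onset, peak,
#'   width_ms) and `overlaps` (data.frame: pair, overlap_ms).
#' @export
measure_burst_stats <- function(rates, bin = 20, time = NULL) {
  if (inherits(rates, "psth")) {
    time <- rates$time; bin <- rates$bin_width; rates <- rates$rate
  }
  rates <- as.matrix(rates)
  if (!is.null(time) && length(time) > 1 && diff(time[1:2]) < bin) {
    ib <- floor(time / bin) + 1L
    rates <- apply(rates, 2, function(col) tapply(col, ib, mean))
  }
  nb <- nrow(rates)
  if (is.null(colnames(rates))) colnames(rates) <- seq_len(ncol(rates))
  above <- sapply(seq_len(ncol(rates)), function(j) {
    pk <- max(rates[, j])
    if (pk <= 0) rep(FALSE, nb) else rates[, j] >= pk / 2
  })
  bursts <- do.call(rbind, lapply(seq_len(ncol(rates)), function(j) {
    if (!any(above[, j]))
      return(NULL)
    idx <- which(above[, j])
    data.frame(profile = colnames(rates)[j],
               onset = (min(idx) - 1) * bin,
               peak = max(rates[, j]),
               width_ms = sum(above[, j]) * bin)
  }))
  if (is.null(bursts))
    bursts <- data.frame(profile = character(), onset = numeric(),
                         peak = numeric(), width_ms = numeric())
  overlaps <- if (ncol(rates) >= 2) {
    do.call(rbind, lapply(seq_len(ncol(rates) - 1L), function(j)
      data.frame(pair = paste(colnames(rates)[j], colnames(rates)[j + 1L],
                              sep = "-"),
                 overlap_ms = sum(above[, j] & above[, j + 1L]) * bin)))
  } else data.frame(pair = character(), overlap_ms = numeric())
  list(bursts = bursts, overlaps = overlaps)
}

#' Write / read a simulation result
#'
#' `write_result()` lays a `chain_sim_result` out as plain-text files in a
#' directory: `raster.csv` (`neuron_id, pool_id, t_ms`), `rates.csv`
#' (binned pool rates), `bursts.json` and `manifest.json` (seed, config
#' hash, outcome).  `read_result()` inverts the write.
#'
#' @param result a `chain_sim_result`.
#' @param path output directory (created if missing).
#' @return `write_result()` returns `path` invisibly; `read_result()` a
#'   `chain_sim_result` (without the live `currents` traces).
#' @export
write_result <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  raster <- result$raster
  names(raster) <- c("neuron_id", "pool_id", "t_ms")
  utils::write.csv(raster, file.path(path, "raster.csv"), row.names = FALSE)
  rates <- data.frame(t_ms = result$bin_time, result$pool_rates,
                      check.names = FALSE)
  utils::write.csv(rates, file.path(path, "rates.csv"), row.names = FALSE)
  jsonlite::write_json(result$bursts, file.path(path, "bursts.json"),
                       dataframe = "rows", digits = NA)
  man <- result$manifest
  man$outcome <- result$outcome
  man$activations <- as.list(result$activations)
  man$motor_events <- result$motor_events
  man$suppressed_motor <- result$suppressed_motor
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  need <- c("raster.csv", "rates.csv", "bursts.json", "manifest.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("missing result file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raster <- utils::read.csv(file.path(path, "raster.csv"))
  if (!all(c("neuron_id", "pool_id", "t_ms") %in% names(raster)))
    stop("raster.csv: expected columns neuron_id, pool_id, t_ms",
         call. = FALSE)
  names(raster) <- c("neuron", "pool", "t")
  rates <- utils::read.csv(file.path(path, "rates.csv"), check.names = FALSE)
  bursts <- jsonlite::read_json(file.path(path, "bursts.json"),
                                simplifyVector = TRUE)
  if (!length(bursts))
    bursts <- data.frame(pool = character(), onset = numeric(),
                         offset = numeric(), peak = numeric(),
                         duration = numeric())
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  act <- unlist(man$activations)
  man$outcome <- lapply(man$outcome, function(x) as.character(unlist(x)))
  structure(list(
    raster = raster,
    pool_rates = as.matrix(rates[, -1, drop = FALSE]),
    bin_time = rates$t_ms,
    bursts = bursts,
    activations = act,
    motor_events = man$motor_events,
    suppressed_motor = man$suppressed_motor,
    outcome = man$outcome,
    currents = NULL,
    manifest = man[c("seed", "duration", "config_hash", "motor_gate",
                     "scenario")]
  ), class = "chain_sim_result")
}

#' Quick look at a simulation result
#'
#' Raster (top) and binned pool rate traces (bottom) in base graphics;
#' colors follow pool order.
#'
#' @param x a `chain_sim_result`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.chain_sim_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  pools <- colnames(x$pool_rates)
  cols <- grDevices::hcl.colors(max(3, length(pools)), "Dark 3")[seq_along(pools)]
  pi <- match(x$raster$pool, pools)
  graphics::plot(x$raster$t, x$raster$neuron, pch = ".", col = cols[pi],
                 xlab = "", ylab = "neuron",
                 xlim = c(0, max(x$bin_time) + 10))
  graphics::matplot(x$bin_time, x$pool_rates, type = "l", lty = 1,
                    col = cols, xlab = "time (ms)", ylab = "pool rate (Hz)")
  graphics::legend("topright", legend = pools, col = cols, lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}
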
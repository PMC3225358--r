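#' Generate (inhomogeneous) Poisson spike trains
#'
#' Draws independent Poisson spike trains from a common rate profile by
#' thinning: per train, the spike count over the window is Poisson with
#' mean `max rate * duration`, candidate times are uniform, and each is
#' accepted with probability `rate(t)/max rate`.  Fully reproducible under
#' `seed`.
#'
#' @param rate either a single non-negative rate in Hz or a vectorized
#'   function of time (ms) returning Hz.
#' @param duration window length, ms (spikes fall in `[0, duration)`).
#' @param n_targets number of independent trains.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param rate_max upper bound of the rate profile (required when `rate`
#'   is a function and its maximum is not obvious; defaults to the maximum
#'   over a 1 ms grid).
#' @return data.frame with columns `train` (1..n_targets) and `t` (ms),
#'   sorted by time.
#' @examples
#' sp <- gen_poisson_train(100, 1000, 10, seed = 1)
#' nrow(sp) / 10   # about 100 spikes per train
#' @export
gen_poisson_train <- function(rate, duration, n_targets, seed = NULL,
                              rate_max = NULL) {
  stopifnot(duration > 0, n_targets >= 1)
  rate_fn <- if (is.function(rate)) rate else {
    if (rate < 0) stop("rate must be non-negative", call. = FALSE)
    local({ r <- rate; function(t) rep(r, length(t)) })
  }
  if (is.null(rate_max)) {
    rate_max <- if (is.function(rate))
      max(rate_fn(seq(0, duration, by = 1))) else rate
  }
  if (rate_max < 0) stop("rate must be non-negative", call. = FALSE)
  with_seed_(seed, {
    if (rate_max == 0)
      return(data.frame(train = integer(), t = numeric()))
    counts <- rpois(n_targets, rate_max * duration / 1000)
    train <- rep(seq_len(n_targets), counts)
    t <- runif(sum(counts), 0, duration)
    keep <- runif(length(t)) < rate_fn(t) / rate_max
    out <- data.frame(train = train[keep], t = t[keep])
    out[order(out$t), , drop = FALSE]
  })
}

#' Gaussian ("bell") rate profile
#'
#' @param peak_rate peak rate, Hz.
#' @param center,width center (ms) and full width at half maximum (ms).
#' @return a vectorized function of time (ms) returning Hz.
#' @export
bell_profile <- function(peak_rate, center, width) {
  if (width <= 0) stop("degenerate bell profile: width must be positive",
                       call. = FALSE)
  sigma <- width / (2 * sqrt(2 * log(2)))
  function(t) peak_rate * exp(-(t - center)^2 / (2 * sigma^2))
}

#' Prefrontal intention burst
#'
#' The chain-selection signal from the prefrontal "intention pool": a
#' bell-shaped high-frequency spike train delivered through external AMPA
#' receptors to a random fraction (default 20%) of the neurons of the
#' chain's first pool.  This is the one external signal that is strong
#' enough on its own to ignite its target pool.
#'
#' @param network a `chain_network`.
#' @param pool target pool id.
#' @param fraction fraction of the pool that is targeted (0 < fraction <= 1).
#' @param peak_rate peak rate of the bell profile, Hz.
#' @param width full width at half maximum of the bell, ms.
#' @param onset time of the profile start, ms (the bell is centred at
#'   `onset + width` and truncated to `[onset, onset + 2*width]`).
#' @param seed RNG seed used to draw the target subset.
#' @return a stimulus event (see [stimulus_event()]).
#' @export
gen_intention_burst <- function(network, pool, fraction = NULL,
                                peak_rate = NULL, width = NULL,
                                onset = 0, seed = NULL) {
  st <- network$config$stimulus$intention
  fraction <- fraction %||% st$fraction
  peak_rate <- peak_rate %||% st$peak_rate
  width <- width %||% st$width
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (width <= 0) stop("degenerate intention burst: width must be positive",
                       call. = FALSE)
  k <- round(fraction * length(pool_neurons(network, pool)))
  if (k < 1) stop("empty target set", call. = FALSE)
  exc <- pool_neurons(network, pool, type = "excitatory")
  targets <- with_seed_(seed, sort(sample(exc, min(k, length(exc)))))
  stimulus_event(channel = "pfc", targets = targets,
                 t_on = onset, t_off = onset + 2 * width,
                 rate = bell_profile(peak_rate, onset + width, width),
                 peak_rate = peak_rate, label = "intention")
}

#' Sensory feedback / motor corollary discharge trains
#'
#' Constant-rate spike trains of fixed duration (default 300 ms, matching
#' the duration of real reaching / grasping / bringing movements) directed
#' to a configured fraction of a pool.  `kind = "sensory"` models
#' proprioceptive-visual feedback delivered through the sensory channel;
#' `kind = "corollary"` models the efference copy returned by premotor /
#' motor areas through the motor channel.
#'
#' @param network a `chain_network`.
#' @param kind `"sensory"` or `"corollary"`.
#' @param pool target pool id.
#' @param onset onset time, ms.
#' @param duration train duration, ms (> 0).
#' @param rate rate per targeted neuron, Hz.
#' @param fraction targeted fraction of the pool.
#' @param seed RNG seed for the target subset.
#' @return a stimulus event.
#' @export
gen_feedback_train <- function(network, kind = c("sensory", "corollary"),
                               pool, onset = 0, duration = NULL,
                               rate = NULL, fraction = NULL, seed = NULL) {
  kind <- match.arg(kind)
  fb <- network$config$stimulus$feedback
  duration <- duration %||% fb$duration
  rate <- rate %||%
    (if (kind == "corollary") fb$rate_corollary %||% fb$rate else fb$rate)
  fraction <- fraction %||%
    (if (kind == "corollary") fb$fraction_corollary %||% fb$fraction
     else fb$fraction)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  k <- max(1L, round(fraction * length(pool_neurons(network, pool))))
  exc <- pool_neurons(network, pool, type = "excitatory")
  targets <- with_seed_(seed, sort(sample(exc, min(k, length(exc)))))
  stimulus_event(channel = if (kind == "sensory") "sensory" else "motor",
                 targets = targets, t_on = onset, t_off = onset + duration,
                 rate = rate, peak_rate = rate, label = kind)
}

#' A timed external stimulus event
#'
#' The atom of a stimulus program: a rate profile delivered over
#' `[t_on, t_off)` to a set of target neurons through one of the four
#' external input channels (`"pfc"` bursts, `"tonic"` sustained
#' prefrontal prediction, `"sensory"`, `"motor"`), each of which drives
#' its own external-AMPA gating variable with a channel-specific weight
#' (see `default_config()$stimulus$channel_weights`).
#'
#' @param channel input channel.
#' @param targets integer neuron ids.
#' @param t_on,t_off window, ms (`t_off > t_on`).
#' @param rate scalar Hz or function of time (ms).
#' @param peak_rate upper bound of `rate` (used by the thinning sampler).
#' @param label free-text tag.
#' @return list of class `stimulus_event`.
#' @export
stimulus_event <- function(channel = c("pfc", "tonic", "sensory", "motor"),
                           targets, t_on, t_off, rate, peak_rate,
                           label = "") {
  channel <- match.arg(channel)
  stopifnot(length(targets) >= 1, t_off > t_on, peak_rate >= 0)
  structure(list(channel = channel, targets = as.integer(targets),
                 t_on = t_on, t_off = t_off, rate = rate,
                 peak_rate = peak_rate, label = label),
            class = "stimulus_event")
}

# Sample the spikes an event contributes to the window [t0, t1).
sample_event_spikes_ <- function(ev, t0, t1) {
  a <- max(t0, ev$t_on); b <- min(t1, ev$t_off)
  if (a >= b || ev$peak_rate <= 0)
    return(data.frame(t = numeric(), target = integer()))
  lam <- ev$peak_rate * (b - a) / 1000
  counts <- rpois(length(ev$targets), lam)
  tot <- sum(counts)
  if (!tot) return(data.frame(t = numeric(), target = integer()))
  tt <- runif(tot, a, b)
  tg <- rep(ev$targets, counts)
  if (is.function(ev$rate)) {
    keep <- runif(tot) < ev$rate(tt) / ev$peak_rate
    tt <- tt[keep]; tg <- tg[keep]
  }
  o <- order(tt)
  data.frame(t = tt[o], target = tg[o])
}

#' Template activity profiles for the chain learning experiment
#'
#' Emulates the population activity profiles of sequentially active
#' parietal pools used to drive the learning network: `n_acts` sequential
#' bell-shaped bursts, each with a half-maximum duration of
#' `burst_duration` (default 300 ms), successive bursts jointly above
#' half-maximum for `overlap` (default 80 ms).  The raw profiles carry a
#' constant baseline, are smoothed with a Gaussian filter of width
#' `filter_sigma`, then baseline-subtracted (so the rate is zero between
#' bursts) and peak-normalized to `peak_rate`.  The construction is
#' deterministic.
#'
#' @param spec list with fields `n_acts`, `burst_duration` (ms),
#'   `overlap` (ms), `peak_rate` (Hz), `filter_sigma` (ms), `baseline`
#'   (Hz), `margin` (ms of silence before the first burst); defaults from
#'   `default_config()$stimulus$template`.
#' @param dt_grid sampling step of the returned profiles, ms.
#' @return list of class `template_profiles`: `time` (ms grid), `rates`
#'   (matrix, one column per act, Hz), and the `spec`.
#' @examples
#' tp <- gen_template_profiles()
#' measure_burst_stats(tp$rates, bin = 20, time = tp$time)
#' @export
gen_template_profiles <- function(spec = default_config()$stimulus$template,
                                  dt_grid = 1) {
  spec <- utils::modifyList(default_config()$stimulus$template, spec)
  if (spec$overlap >= spec$burst_duration)
    stop("overlap must be smaller than burst_duration", call. = FALSE)
  stopifnot(spec$n_acts >= 1, spec$burst_duration > 0, spec$peak_rate > 0,
            spec$filter_sigma >= 0)
  fwhm_k <- 2 * sqrt(2 * log(2))
  sigma_tot <- spec$burst_duration / fwhm_k
  if (sigma_tot <= spec$filter_sigma)
    stop("filter_sigma too large for the requested burst_duration",
         call. = FALSE)
  sigma_base <- sqrt(sigma_tot^2 - spec$filter_sigma^2)
  spacing <- spec$burst_duration - spec$overlap
  centers <- spec$margin + (seq_len(spec$n_acts) - 1) * spacing
  total <- spec$margin * 2 + max(centers) - min(centers) + spec$burst_duration
  time <- seq(0, total, by = dt_grid)

  # Gaussian filter kernel on the sampling grid
  half <- ceiling(4 * spec$filter_sigma / dt_grid)
  kern <- dnorm(seq(-half, half) * dt_grid, sd = max(spec$filter_sigma, 1e-9))
  kern <- kern / sum(kern)

  rates <- sapply(centers, function(cc) {
    raw <- spec$baseline + exp(-(time - cc)^2 / (2 * sigma_base^2))
    sm <- if (spec$filter_sigma > 0) {
      padded <- c(rep(raw[1], half), raw, rep(raw[length(raw)], half))
      stats::filter(padded, kern, sides = 2)[(half + 1):(half + length(raw))]
    } else raw
    sm <- as.numeric(sm) - spec$baseline       # baseline subtraction
    sm <- pmax(sm, 0)
    spec$peak_rate * sm / max(sm)              # peak normalization
  })
  structure(list(time = time, rates = rates, spec = spec),
            class = "template_profiles")
}
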
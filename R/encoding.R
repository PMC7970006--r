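#' Discrete simulation time grid
#'
#' The clock-driven simulator and all encoders operate on a uniform time grid.
#' Step `k` corresponds to time `t = (k - 1) * dt`, so the first step sits at
#' `t = 0` and the last at `window - dt`.
#'
#' @param window Encoding/simulation window length in ms.
#' @param dt Time step in ms (default 0.5 ms).
#' @return An object of class `time_grid` with fields `dt`, `window`,
#'   `n_steps`, and `times` (step times in ms).
#' @export
time_grid <- function(window, dt = 0.5) {
  stopifnot(dt > 0, window > 0)
  n_steps <- window / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("`window` must be an integer multiple of `dt`", call. = FALSE)
  }
  n_steps <- as.integer(round(n_steps))
  structure(
    list(dt = dt, window = window, n_steps = n_steps,
         times = (seq_len(n_steps) - 1) * dt),
    class = "time_grid"
  )
}

#' Normalize an 8-bit image to [0, 1]
#'
#' Divides intensities by the maximum representable value (255), the
#' normalization used by the time-to-first-spike and burst encoders.
#'
#' @param img Numeric matrix of pixel intensities in \[0, 255\].
#' @return Numeric matrix with values in \[0, 1\], same shape.
#' @export
normalize_image <- function(img) {
  img <- as.matrix(img)
  if (any(img < 0 | img > 255)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  img / 255
}

# ---- parameter constructors -------------------------------------------------

#' Encoder parameter sets
#'
#' Constructors for the per-scheme encoder parameters. Defaults are the
#' simulation values in general use for 8-bit images: rate down-scaling
#' `lambda = 4` (max rate 63.75 Hz); TTFS threshold constant `theta0 = 1`
#' with decay constants `tau_th = 6` ms and `tau_s = 15` ms; 8 phases for
#' 8-bit pixels; bursts of at most `n_max = 5` spikes with inter-spike
#' intervals confined to \[`t_min` = 2, `t_max` = 10\] ms.
#'
#' @param lambda_scale Dimensionless down-scaling factor applied to pixel
#'   intensities before interpreting them as firing rates in Hz.
#' @param theta0 TTFS threshold constant (dimensionless, applied to
#'   normalized pixels).
#' @param tau_th TTFS threshold decay time constant in ms.
#' @param tau_s TTFS spike-weight decay time constant in ms.
#' @param n_phases Period of the phase code in steps (8 for 8-bit pixels).
#' @param n_max Maximum number of spikes in a burst.
#' @param t_max,t_min Maximum/minimum burst inter-spike interval in ms.
#' @return A parameter list of class `rate_params`, `ttfs_params`,
#'   `phase_params`, or `burst_params`.
#' @name encoder_params
NULL

#' @rdname encoder_params
#' @export
rate_params <- function(lambda_scale = 4) {
  stopifnot(lambda_scale > 0)
  structure(list(lambda_scale = lambda_scale), class = "rate_params")
}

#' @rdname encoder_params
#' @export
ttfs_params <- function(theta0 = 1, tau_th = 6, tau_s = 15) {
  stopifnot(theta0 > 0, tau_th > 0, tau_s > 0)
  structure(list(theta0 = theta0, tau_th = tau_th, tau_s = tau_s),
            class = "ttfs_params")
}

#' @rdname encoder_params
#' @export
phase_params <- function(n_phases = 8) {
  stopifnot(n_phases >= 1)
  structure(list(n_phases = as.integer(n_phases)), class = "phase_params")
}

#' @rdname encoder_params
#' @export
burst_params <- function(n_max = 5, t_max = 10, t_min = 2) {
  stopifnot(n_max >= 1, t_max >= t_min, t_min > 0)
  structure(list(n_max = n_max, t_max = t_max, t_min = t_min),
            class = "burst_params")
}

new_spike_raster <- function(spikes, spike_weight, grid, scheme) {
  stopifnot(ncol(spikes) == grid$n_steps,
            length(spike_weight) == grid$n_steps)
  structure(
    list(spikes = spikes, spike_weight = spike_weight,
         dt = grid$dt, times = grid$times, scheme = scheme),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %s coding: %d inputs x %d steps (dt = %g ms), %d spikes\n",
              x$scheme, nrow(x$spikes), ncol(x$spikes), x$dt, sum(x$spikes)))
  invisible(x)
}

#' Firing rate assigned to a pixel by the rate encoder
#'
#' The rate code interprets a down-scaled pixel intensity as a firing rate in
#' Hz: `rate = intensity / lambda`. For 8-bit pixels and the default
#' `lambda = 4` the rates are confined between 0 and 63.75 Hz.
#'
#' @param intensity Pixel intensity in \[0, 255\] (vectorized).
#' @param params A [rate_params()] object.
#' @return Firing rate(s) in Hz.
#' @export
rate_coding_rate <- function(intensity, params = rate_params()) {
  stopifnot(all(intensity >= 0), all(intensity <= 255))
  intensity / params$lambda_scale
}

#' Rate (Poisson) spike encoding
#'
#' Each pixel is converted into a stochastic spike train whose per-step spike
#' probability is `rate * dt` with `rate = intensity / lambda` in Hz — a
#' Bernoulli-per-step approximation of a Poisson process, realized by
#' comparing the scaled pixel against uniform random numbers. Spike weights
#' are uniformly 1. Uses the current R random stream; seed with `set.seed()`
#' for reproducibility.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @param params A [rate_params()] object.
#' @param grid A [time_grid()].
#' @return A `spike_raster`.
#' @export
encode_rate <- function(img, params = rate_params(), grid = time_grid(100)) {
  rates <- rate_coding_rate(as.vector(img), params)  # Hz
  p <- rates * grid$dt / 1000
  if (any(p > 1)) {
    bad <- which.max(p)
    stop(sprintf(
      "per-step spike probability %.3f > 1 for pixel %d (intensity %g, lambda %g, dt %g ms)",
      p[bad], bad, as.vector(img)[bad], params$lambda_scale, grid$dt),
      call. = FALSE)
  }
  n <- length(p)
  u <- matrix(stats::runif(n * grid$n_steps), nrow = n)
  spikes <- u < p
  new_spike_raster(spikes, rep(1, grid$n_steps), grid, "rate")
}

#' TTFS decaying threshold
#'
#' The time-to-first-spike encoder compares each normalized pixel against an
#' exponentially decaying threshold `P_th(t) = theta0 * exp(-t / tau_th)`;
#' brighter pixels cross earlier and therefore spike earlier.
#'
#' @param t Time in ms (vectorized).
#' @param params A [ttfs_params()] object.
#' @return Threshold value(s).
#' @export
ttfs_threshold <- function(t, params = ttfs_params()) {
  stopifnot(all(t >= 0))
  params$theta0 * exp(-t / params$tau_th)
}

#' TTFS spike weight
#'
#' Decoding weight carried by a spike fired at time `t`:
#' `w_s(t) = exp(-t / tau_s)`. Earlier spikes carry larger weight, so the
#' spike time itself encodes the amount of information delivered to the
#' postsynaptic neurons.
#'
#' @inheritParams ttfs_threshold
#' @return Spike weight(s) in (0, 1].
#' @export
spike_weight_ttfs <- function(t, params = ttfs_params()) {
  stopifnot(all(t >= 0))
  exp(-t / params$tau_s)
}

#' Time-to-first-spike encoding
#'
#' Each normalized pixel fires once, at the first grid step whose decaying
#' threshold it strictly exceeds, and is then inhibited from spiking again;
#' pixels that never cross the threshold within the window stay silent.
#' The raster's spike-weight sequence is `exp(-t / tau_s)`. Deterministic.
#'
#' @param img Numeric matrix of normalized values in \[0, 1\]
#'   (see [normalize_image()]).
#' @param params A [ttfs_params()] object.
#' @param grid A [time_grid()]; defaults to the 20 ms TTFS window.
#' @return A `spike_raster` with per-neuron spike counts in \{0, 1\}.
#' @export
encode_ttfs <- function(img, params = ttfs_params(), grid = time_grid(20)) {
  v <- as.vector(img)
  stopifnot(all(v >= 0), all(v <= 1))
  th <- ttfs_threshold(grid$times, params)
  # first step index at which v > th(t); threshold at t = 0 equals theta0 so
  # even a saturated pixel fires no earlier than the first decayed step
  spikes <- matrix(FALSE, length(v), grid$n_steps)
  cross <- outer(v, th, ">")
  first <- apply(cross, 1, function(row) if (any(row)) which.max(row) else NA_integer_)
  has <- !is.na(first)
  spikes[cbind(which(has), first[has])] <- TRUE
  new_spike_raster(spikes, spike_weight_ttfs(grid$times, params), grid, "ttfs")
}

#' Phase-code spike weight
#'
#' Periodic decoding weight `w_s(t) = 2^-(1 + mod(t - 1, 8))` for step index
#' `t >= 1`: the weight of phase 1 is 1/2 (most-significant bit) down to
#' 2^-8 at phase 8, then the cycle restarts.
#'
#' @param t Step index (1-based, vectorized).
#' @param params A [phase_params()] object.
#' @return Spike weight(s).
#' @export
spike_weight_phase <- function(t, params = phase_params()) {
  stopifnot(all(t >= 1))
  2^-(1 + (t - 1) %% params$n_phases)
}

#' Phase encoding
#'
#' Each pixel's 8-bit binary representation is emitted as one spike per "1"
#' bit, most-significant bit at phase 1, and the 8-step pattern repeats for
#' the whole window (a final partial period is truncated). The spike weight
#' sequence [spike_weight_phase()] encodes the significance of each bit.
#' Phase coding uses one grid step per phase (1 ms steps by default).
#' Deterministic.
#'
#' @param img Integer matrix of intensities in \[0, 2^n_phases).
#' @param params A [phase_params()] object.
#' @param grid A [time_grid()]; default 30 ms window at 1 ms steps.
#' @return A `spike_raster`.
#' @export
encode_phase <- function(img, params = phase_params(), grid = time_grid(30, dt = 1)) {
  v <- as.integer(round(as.vector(img)))
  nb <- params$n_phases
  if (any(v < 0) || any(v >= 2^nb)) {
    stop(sprintf("intensities must fit in %d bits", nb), call. = FALSE)
  }
  # bit at phase k (1 = MSB): floor(v / 2^(nb - k)) mod 2
  bits <- matrix(FALSE, length(v), nb)        # n_pixels x nb, phase 1 = MSB
  for (k in seq_len(nb)) bits[, k] <- (v %/% 2^(nb - k)) %% 2 == 1
  phase_of_step <- 1 + (seq_len(grid$n_steps) - 1) %% nb
  spikes <- bits[, phase_of_step, drop = FALSE]
  new_spike_raster(spikes, spike_weight_phase(seq_len(grid$n_steps), params),
                   grid, "phase")
}

#' Burst spike count
#'
#' Number of spikes in the burst emitted for a normalized pixel `P`:
#' `N_s(P) = ceiling(n_max * P)`. Zero only for a fully dark pixel.
#'
#' @param P Normalized pixel value(s) in \[0, 1\].
#' @param params A [burst_params()] object.
#' @return Integer spike count(s).
#' @export
burst_spike_count <- function(P, params = burst_params()) {
  stopifnot(all(P >= 0), all(P <= 1))
  as.integer(ceiling(params$n_max * P))
}

#' Burst inter-spike interval
#'
#' ISI of the burst for normalized pixel `P`:
#' `ISI(P) = ceiling(-(t_max - t_min) * P + t_max)` ms when the burst holds
#' more than one spike, `t_max` otherwise. Confined to \[`t_min`, `t_max`\]
#' and non-increasing in `P` — brighter pixels give denser bursts.
#'
#' @inheritParams burst_spike_count
#' @return ISI value(s) in ms.
#' @export
burst_isi <- function(P, params = burst_params()) {
  ns <- burst_spike_count(P, params)
  isi <- ceiling(-(params$t_max - params$t_min) * P + params$t_max)
  isi <- pmin(pmax(isi, params$t_min), params$t_max)
  isi[ns <= 1] <- params$t_max
  isi
}

#' Burst encoding
#'
#' Each normalized pixel emits a burst of `N_s(P)` spikes starting at the
#' first grid step (t = 0), consecutive spikes separated by `ISI(P)` ms;
#' spikes falling beyond the window are truncated. Spike weights are
#' uniformly 1. Deterministic.
#'
#' @param img Numeric matrix of normalized values in \[0, 1\].
#' @param params A [burst_params()] object.
#' @param grid A [time_grid()]; defaults to a 20 ms window.
#' @return A `spike_raster`.
#' @export
encode_burst <- function(img, params = burst_params(), grid = time_grid(20)) {
  v <- as.vector(img)
  stopifnot(all(v >= 0), all(v <= 1))
  ns <- burst_spike_count(v, params)
  isi <- burst_isi(v, params)
  spikes <- matrix(FALSE, length(v), grid$n_steps)
  for (i in which(ns > 0)) {
    tt <- (seq_len(ns[i]) - 1) * isi[i]         # ms, first spike at t = 0
    steps <- round(tt / grid$dt) + 1
    steps <- steps[steps <= grid$n_steps]
    spikes[i, steps] <- TRUE
  }
  new_spike_raster(spikes, rep(1, grid$n_steps), grid, "burst")
}

#' Encode an image under a named coding scheme
#'
#' Dispatcher over the four encoders. `rate` and `phase` consume raw 8-bit
#' intensities; `ttfs` and `burst` normalize the image first.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @param scheme One of `"rate"`, `"ttfs"`, `"phase"`, `"burst"`.
#' @param params Encoder parameter object for the scheme (defaults used if
#'   `NULL`).
#' @param grid A [time_grid()]; scheme default windows used if `NULL`
#'   (rate 100 ms at 0.5 ms; ttfs/burst 20 ms at 0.5 ms; phase 30 ms at 1 ms).
#' @return A `spike_raster`.
#' @export
encode <- function(img, scheme = c("rate", "ttfs", "phase", "burst"),
                   params = NULL, grid = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    rate  = encode_rate(img, params %||% rate_params(),
                        grid %||% time_grid(100)),
    ttfs  = encode_ttfs(normalize_image(img), params %||% ttfs_params(),
                        grid %||% time_grid(20)),
    phase = encode_phase(img, params %||% phase_params(),
                         grid %||% time_grid(30, dt = 1)),
    burst = encode_burst(normalize_image(img), params %||% burst_params(),
                         grid %||% time_grid(20))
  )
}

#' Spike raster as an event list
#'
#' One row per spike: input neuron index, spike time in ms, and the decoding
#' weight carried by the spike. This tabular form is the interchange format
#' for raster export ([write_spike_events()]).
#'
#' @param raster A `spike_raster`.
#' @return A tibble with columns `neuron`, `time_ms`, `weight`.
#' @export
raster_events <- function(raster) {
  idx <- which(raster$spikes, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(
    neuron = as.integer(idx[, 1]),
    time_ms = raster$times[idx[, 2]],
    weight = raster$spike_weight[idx[, 2]]
  )
}

#' Write / read spike events as CSV
#'
#' Plain-text event-list serialization with a versioned header comment line
#' (`# spikecoding events v1 scheme=<scheme> dt=<dt> window=<ms>`).
#' `read_spike_events()` returns the events tibble with those fields as
#' attributes.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `write_spike_events()` returns `path` invisibly;
#'   `read_spike_events()` a tibble of events.
#' @export
write_spike_events <- function(raster, path) {
  header <- sprintf("# spikecoding events v1 scheme=%s dt=%g window=%g n_inputs=%d",
                    raster$scheme, raster$dt,
                    raster$dt * length(raster$times), nrow(raster$spikes))
  ev <- raster_events(raster)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(ev, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# spikecoding events v1", header)) {
    stop("not a spikecoding v1 event file: ", path, call. = FALSE)
  }
  ev <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  for (item in kv) {
    parts <- strsplit(item, "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(parts[2]))
    attr(ev, parts[1]) <- if (is.na(val)) parts[2] else val
  }
  ev
}
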
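#' Neuron, synapse, and adaptation parameters
#'
#' Constructors for the leaky integrate-and-fire (LIF) neuron, the
#' conductance synapse, the adaptive firing threshold, and the fixed
#' excitatory/inhibitory coupling of the winner-take-all circuit.
#'
#' The LIF membrane obeys `tau_m * dv/dt = -(v - v_rest) + g`, integrated
#' with an exponential-Euler step; a neuron fires when `v >= v_th + theta`
#' (where `theta` is its adaptive threshold offset), is reset to `v_reset`,
#' and is silent for `t_refrac` ms. Synaptic conductance decays as
#' `exp(-dt / tau_g)` and jumps by the synaptic input at spike arrival.
#' Whenever a neuron fires its threshold offset grows by `theta_plus` and
#' then decays slowly (time constant `theta_decay`), which keeps the
#' winner-take-all competition fair across neurons.
#'
#' @param tau_m Membrane time constant in ms.
#' @param v_th Base firing threshold in mV.
#' @param v_reset,v_rest Reset and resting potentials in mV.
#' @param t_refrac Refractory period in ms.
#' @param tau_g Conductance decay time constant in ms.
#' @param theta_plus Threshold adaptation increment in mV.
#' @param theta_decay Threshold decay time constant in ms (slow relative to
#'   one image window).
#' @param w_ei Fixed excitatory-to-inhibitory coupling strength (one-to-one).
#' @param w_ie Fixed inhibitory-to-excitatory coupling strength
#'   (each inhibitory neuron targets all excitatory neurons but its source).
#' @param input_gain Conductance-to-membrane coupling gain applied to the
#'   summed input-synapse drive (mV per unit summed weight). Sets the
#'   operating point of the winner-take-all competition: the peak drive of
#'   a typical input pattern should sit a small factor above the firing
#'   threshold so that neurons with better-matching weights cross first
#'   and lateral inhibition can silence the rest.
#' @return A parameter list of the corresponding class.
#' @name neuron_params
NULL

#' @rdname neuron_params
#' @export
lif_params <- function(tau_m = 10, v_th = 0.5, v_reset = 0, v_rest = 0,
                       t_refrac = 2) {
  stopifnot(tau_m > 0, v_th > v_reset, t_refrac >= 0)
  structure(list(tau_m = tau_m, v_th = v_th, v_reset = v_reset,
                 v_rest = v_rest, t_refrac = t_refrac), class = "lif_params")
}

#' @rdname neuron_params
#' @export
synapse_params <- function(tau_g = 30) {
  stopifnot(tau_g > 0)
  structure(list(tau_g = tau_g), class = "synapse_params")
}

#' @rdname neuron_params
#' @export
adapt_params <- function(theta_plus = 0.008, theta_decay = 1e4) {
  stopifnot(theta_plus >= 0, theta_decay > 0)
  structure(list(theta_plus = theta_plus, theta_decay = theta_decay),
            class = "adapt_params")
}

#' @rdname neuron_params
#' @export
coupling_params <- function(w_ei = 15, w_ie = 2, input_gain = 0.1) {
  stopifnot(w_ei >= 0, w_ie >= 0, input_gain > 0)
  structure(list(w_ei = w_ei, w_ie = w_ie, input_gain = input_gain),
            class = "coupling_params")
}

#' Two-layer winner-take-all topology
#'
#' Builds the input-to-excitatory weight matrix and the fixed lateral
#' wiring: every excitatory neuron drives one dedicated inhibitory neuron
#' (one-to-one), and each inhibitory neuron inhibits all excitatory neurons
#' except its source. Input weights are initialized uniformly in (0, 1)
#' from the current R random stream.
#'
#' @param n_input Number of input neurons (pixels).
#' @param n_exc Number of excitatory neurons (equals the number of
#'   inhibitory neurons).
#' @param coupling A [coupling_params()] object.
#' @return An object of class `snn_topology` with fields `n_input`, `n_exc`,
#'   `n_inh`, `W` (input weights in \[0, 1\]), `coupling`, `prune_mask`
#'   (logical, `TRUE` marks a pruned-and-frozen synapse), and `saf`
#'   (stuck-at-fault state, `NULL` when absent).
#' @export
build_topology <- function(n_input, n_exc, coupling = coupling_params()) {
  stopifnot(n_input >= 1, n_exc >= 1)
  W <- matrix(stats::runif(n_input * n_exc), n_input, n_exc)
  structure(
    list(n_input = as.integer(n_input), n_exc = as.integer(n_exc),
         n_inh = as.integer(n_exc), W = W, coupling = coupling,
         prune_mask = matrix(FALSE, n_input, n_exc), saf = NULL),
    class = "snn_topology"
  )
}

#' @export
print.snn_topology <- function(x, ...) {
  cat(sprintf("<snn_topology> %d inputs -> %d exc <-> %d inh (WTA), %.1f%% connectivity\n",
              x$n_input, x$n_exc, x$n_inh, connectivity(x$prune_mask)))
  invisible(x)
}

#' Fresh network state
#'
#' Membrane potentials at rest, zero conductances and refractory counters,
#' and (unless supplied) zero adaptive-threshold offsets. Between images the
#' transient state (v, g, refractory) is reset while `theta` and the weights
#' persist.
#'
#' @param topo An `snn_topology`.
#' @param lif A [lif_params()] object.
#' @param theta Optional vector of adaptive threshold offsets to carry over.
#' @return An object of class `snn_state`.
#' @export
network_state <- function(topo, lif = lif_params(), theta = NULL) {
  n_exc <- topo$n_exc
  structure(
    list(
      v_exc = rep(lif$v_rest, n_exc),
      v_inh = rep(lif$v_rest, topo$n_inh),
      theta = theta %||% rep(0, n_exc),
      g_e = rep(0, n_exc), g_i = rep(0, n_exc), g_inh = rep(0, topo$n_inh),
      refrac_exc = rep(0L, n_exc), refrac_inh = rep(0L, topo$n_inh),
      t = 0L
    ),
    class = "snn_state"
  )
}

#' Synaptic input from one raster column
#'
#' The simplified post-synaptic potential: input neurons contribute only at
#' their firing step (the effect is not accumulated over time), weighted by
#' the spike weight of that step —
#' `z_j(t) = w_s(t) * sum_i w_ij * s_i(t)`.
#'
#' @param spikes_t Logical/0-1 vector of input spikes at the current step.
#' @param w_s_t Spike weight at the current step (scalar).
#' @param W Input weight matrix (`n_input` x `n_exc`).
#' @return Numeric vector of synaptic drive per excitatory neuron.
#' @export
synaptic_input <- function(spikes_t, w_s_t, W) {
  stopifnot(length(spikes_t) == nrow(W))
  as.vector(w_s_t * crossprod(W, as.numeric(spikes_t)))
}

#' One LIF integration step for a neuron population
#'
#' Exponential-Euler update: conductances decay by `exp(-dt / tau_g)` and
#' jump by the incoming drive, the membrane relaxes toward
#' `v_rest + (g_e - g_i)`, neurons at or above their effective threshold
#' (`v_th + theta`) fire, reset to `v_reset`, and enter the refractory
#' period during which the membrane is clamped.
#'
#' @param v Membrane potentials (mV).
#' @param g_e,g_i Excitatory and inhibitory conductance traces.
#' @param refrac Remaining refractory steps (integer vector).
#' @param z_e,z_i Excitatory / inhibitory synaptic input at this step.
#' @param lif A [lif_params()] object.
#' @param syn A [synapse_params()] object.
#' @param dt Time step in ms.
#' @param theta Adaptive threshold offsets (0 for non-adaptive populations).
#' @return List with updated `v`, `g_e`, `g_i`, `refrac`, and logical
#'   `fired`.
#' @export
lif_step <- function(v, g_e, g_i, refrac, z_e, z_i = 0, lif, syn, dt,
                     theta = 0) {
  g_e <- g_e * exp(-dt / syn$tau_g) + z_e
  g_i <- g_i * exp(-dt / syn$tau_g) + z_i
  active <- refrac <= 0L
  dv <- (dt / lif$tau_m) * (-(v - lif$v_rest) + (g_e - g_i))
  v[active] <- v[active] + dv[active]
  fired <- active & (v >= lif$v_th + theta)
  v[fired] <- lif$v_reset
  refrac[fired] <- as.integer(round(lif$t_refrac / dt))
  refrac[!fired & !active] <- refrac[!fired & !active] - 1L
  list(v = v, g_e = g_e, g_i = g_i, refrac = refrac, fired = fired)
}

#' Adaptive-threshold update
#'
#' Threshold offsets decay exponentially each step and grow by
#' `theta_plus` for neurons that just fired.
#'
#' @param theta Threshold offsets (mV).
#' @param fired Logical vector of spikes this step.
#' @param adapt An [adapt_params()] object.
#' @param dt Time step in ms.
#' @return Updated `theta`.
#' @export
adapt_threshold <- function(theta, fired, adapt, dt) {
  theta <- theta * exp(-dt / adapt$theta_decay)
  theta[fired] <- theta[fired] + adapt$theta_plus
  theta
}

#' Simulate one image window
#'
#' Runs the full clock-driven loop for a single image: encode, then per
#' step compute the synaptic drive, advance the excitatory population,
#' relay excitatory spikes one-to-one to the inhibitory population, apply
#' lateral inhibition (with one step of synaptic delay) to all excitatory
#' neurons but the source, and update the adaptive thresholds. In training
#' mode the accumulated STDP updates are applied at the end of the window
#' through the hook pipeline (quantize, programming noise, clip, pruning,
#' stuck-at-fault). Transient state is reset at window start; `theta` and
#' the weights persist across images.
#'
#' Synaptic operations (SOPs) are counted as one per spike per traversed
#' synapse — input spikes times the number of unpruned synapses on their
#' row, one per excitatory spike (its dedicated inhibitory synapse),
#' `n_exc - 1` per inhibitory spike — plus, in training mode, one per
#' synaptic weight actually updated.
#'
#' @param img Integer matrix of pixel intensities in \[0, 255\].
#' @param cfg A [scheme_config()].
#' @param topo An `snn_topology`.
#' @param state An `snn_state` (its `theta` is carried in; pass the state
#'   returned by the previous call to persist adaptation).
#' @param mode `"infer"` (weights frozen) or `"train"` (STDP on).
#' @param hooks Optional [update_hooks()] applied to the weight update.
#' @param window Override of the window length in ms (defaults to the
#'   scheme's training or inference window according to `mode`).
#' @return List with updated `topo`, `state`, and `trace` — a list holding
#'   `input_spikes`, `output_spikes`, `inh_spikes`, `sops`, `n_updates`,
#'   `per_neuron_counts`, and `post_times` (excitatory spike times, ms).
#' @export
run_window <- function(img, cfg, topo, state = NULL,
                       mode = c("infer", "train"), hooks = NULL,
                       window = NULL) {
  mode <- match.arg(mode)
  window <- window %||% if (mode == "train") cfg$train_window else cfg$infer_window
  grid <- time_grid(window, dt = cfg$dt)
  raster <- encode(img, cfg$scheme, cfg$encoder, grid)
  state <- network_state(topo, cfg$lif, theta = state$theta)

  n_exc <- topo$n_exc
  S <- raster$spikes
  storage.mode(S) <- "double"
  Wt <- t(topo$W)
  w_s <- raster$spike_weight
  lif <- cfg$lif; syn <- cfg$syn; adapt <- cfg$adapt
  w_ei <- topo$coupling$w_ei; w_ie <- topo$coupling$w_ie
  g_in <- topo$coupling$input_gain

  exc_fired <- matrix(FALSE, n_exc, grid$n_steps)
  inh_prev <- rep(0, n_exc)
  inh_total <- 0L

  for (k in seq_len(grid$n_steps)) {
    z_e <- g_in * as.vector(Wt %*% S[, k]) * w_s[k]
    # lateral inhibition from last step's inhibitory spikes, all-but-self
    z_i <- w_ie * (sum(inh_prev) - inh_prev)
    ex <- lif_step(state$v_exc, state$g_e, state$g_i, state$refrac_exc,
                   z_e, z_i, lif, syn, grid$dt, state$theta)
    state$v_exc <- ex$v; state$g_e <- ex$g_e; state$g_i <- ex$g_i
    state$refrac_exc <- ex$refrac
    exc_fired[, k] <- ex$fired

    ih <- lif_step(state$v_inh, state$g_inh, 0, state$refrac_inh,
                   w_ei * as.numeric(ex$fired), 0, lif, syn, grid$dt)
    state$v_inh <- ih$v; state$g_inh <- ih$g_e; state$refrac_inh <- ih$refrac
    inh_prev <- as.numeric(ih$fired)
    inh_total <- inh_total + sum(ih$fired)

    state$theta <- adapt_threshold(state$theta, ex$fired, adapt, grid$dt)
  }
  state$t <- grid$n_steps

  n_updates <- 0L
  if (mode == "train") {
    delta <- stdp_window_delta(raster, exc_fired, grid, topo$W, cfg$stdp)
    upd <- apply_updates(topo$W, delta, hooks,
                         prune_mask = topo$prune_mask, saf = topo$saf)
    topo$W <- upd$W
    topo$prune_mask <- upd$prune_mask
    n_updates <- upd$n_updates
  }

  per_neuron <- rowSums(exc_fired)
  in_per_row <- rowSums(S)
  fan_out <- rowSums(!topo$prune_mask)
  input_spikes <- sum(in_per_row)
  output_spikes <- sum(per_neuron)
  sops <- sum(in_per_row * fan_out) + output_spikes * 1 +
    inh_total * (n_exc - 1) + n_updates

  post_idx <- which(exc_fired, arr.ind = TRUE)
  trace <- list(
    input_spikes = input_spikes,
    output_spikes = output_spikes,
    inh_spikes = inh_total,
    sops = sops,
    n_updates = n_updates,
    per_neuron_counts = per_neuron,
    post_times = tibble::tibble(neuron = as.integer(post_idx[, 1]),
                                time_ms = grid$times[post_idx[, 2]]),
    window = window
  )
  list(topo = topo, state = state, trace = trace)
}
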
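#' STDP parameters
#'
#' Simplified spike-timing-dependent plasticity: a presynaptic spike
#' preceding a postsynaptic spike potentiates the synapse by
#' `mu_plus * w * (1 - w)`; a presynaptic spike following it depresses by
#' `mu_minus * w * (1 - w)`. Pre spikes outside the learning time window of
#' a post spike contribute nothing. Note the depression branch: taken
#' literally, both branches of the rule are positive; here the
#' post-before-pre branch is interpreted as depression of that magnitude,
#' since an all-potentiating rule would drive every weight to saturation
#' and no receptive fields could form.
#'
#' @param mu_plus,mu_minus Potentiation/depression learning rates
#'   (dimensionless, nonnegative).
#' @param window_len Learning time window in ms.
#' @param rule Pair multiplicity: `"all"` (every in-window pre/post pair
#'   contributes) or `"nearest"` (only the nearest pre spike on each side
#'   of every post spike).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(mu_plus = 0.02, mu_minus = 0.002, window_len = 20,
                        rule = c("all", "nearest")) {
  stopifnot(mu_plus >= 0, mu_minus >= 0, window_len > 0)
  structure(list(mu_plus = mu_plus, mu_minus = mu_minus,
                 window_len = window_len, rule = match.arg(rule)),
            class = "stdp_params")
}

#' STDP weight change for one spike pair
#'
#' @param w Current synaptic weight(s) in \[0, 1\].
#' @param t_pre,t_post Pre/post firing times in ms.
#' @param params An [stdp_params()] object.
#' @return Signed weight change; zero when the pre spike lies outside the
#'   learning window of the post spike or the two coincide.
#' @export
stdp_delta <- function(w, t_pre, t_post, params = stdp_params()) {
  stopifnot(all(w >= 0), all(w <= 1))
  dt <- t_post - t_pre
  base <- w * (1 - w)
  out <- numeric(length(base))
  pot <- dt > 0 & dt <= params$window_len
  dep <- dt < 0 & -dt <= params$window_len
  out[pot] <- params$mu_plus * base[pot]
  out[dep] <- -params$mu_minus * base[dep]
  out
}

#' Collect in-window pre/post spike pairs
#'
#' For every postsynaptic spike, the presynaptic spikes within
#' `window_len` ms before it (potentiating) or after it (depressing).
#' Ordering is deterministic: pre neuron, post neuron, pre time, post time.
#'
#' @param t_pre Tibble/data frame of presynaptic events with columns
#'   `neuron`, `time_ms`.
#' @param t_post Tibble/data frame of postsynaptic events with columns
#'   `neuron`, `time_ms`.
#' @param window_len Learning window in ms.
#' @return A tibble with columns `pre_neuron`, `post_neuron`, `t_pre`,
#'   `t_post`, and `type` (`"pot"`/`"dep"`).
#' @export
collect_pairs <- function(t_pre, t_post, window_len = 20) {
  if (nrow(t_pre) == 0 || nrow(t_post) == 0) {
    return(tibble::tibble(pre_neuron = integer(), post_neuron = integer(),
                          t_pre = numeric(), t_post = numeric(),
                          type = character()))
  }
  pairs <- tidyr::crossing(
    tibble::tibble(pre_neuron = t_pre$neuron, t_pre = t_pre$time_ms),
    tibble::tibble(post_neuron = t_post$neuron, t_post = t_post$time_ms)
  )
  d <- pairs$t_post - pairs$t_pre
  keep <- d != 0 & abs(d) <= window_len
  pairs <- pairs[keep, ]
  pairs$type <- ifelse(pairs$t_post > pairs$t_pre, "pot", "dep")
  dplyr::arrange(
    pairs[, c("pre_neuron", "post_neuron", "t_pre", "t_post", "type")],
    .data$pre_neuron, .data$post_neuron, .data$t_pre, .data$t_post
  )
}

# Accumulated STDP delta for a whole window, computed from in-window pair
# counts (equivalent to summing stdp_delta over collect_pairs, but linear in
# spikes): delta_ij = w(1-w) * (mu+ * n_pot_ij - mu- * n_dep_ij).
stdp_window_delta <- function(raster, exc_fired, grid, W, stdp) {
  post_idx <- which(exc_fired, arr.ind = TRUE)
  if (nrow(post_idx) == 0) return(matrix(0, nrow(W), ncol(W)))
  S <- raster$spikes
  storage.mode(S) <- "double"
  L <- as.integer(round(stdp$window_len / grid$dt))
  n_steps <- grid$n_steps
  # cumulative pre-spike counts per input: cs[, k+1] = spikes in steps 1..k
  cs <- cbind(0, t(apply(S, 1, cumsum)))
  counts_between <- function(a, b) {
    # pre spikes in steps [a, b], clamped to the grid; 0 when empty
    a <- max(a, 1L); b <- min(b, n_steps)
    if (a > b) return(numeric(nrow(S)))
    cs[, b + 1] - cs[, a]
  }
  n_pot <- matrix(0, nrow(W), ncol(W))
  n_dep <- matrix(0, nrow(W), ncol(W))
  if (stdp$rule == "all") {
    for (r in seq_len(nrow(post_idx))) {
      j <- post_idx[r, 1]; k <- post_idx[r, 2]
      n_pot[, j] <- n_pot[, j] + counts_between(k - L, k - 1L)
      n_dep[, j] <- n_dep[, j] + counts_between(k + 1L, k + L)
    }
  } else {
    # nearest pre spike on each side of every post spike
    for (r in seq_len(nrow(post_idx))) {
      j <- post_idx[r, 1]; k <- post_idx[r, 2]
      for (i in which(rowSums(S) > 0)) {
        ks <- which(S[i, ] > 0)
        before <- ks[ks >= k - L & ks < k]
        after <- ks[ks > k & ks <= k + L]
        if (length(before)) n_pot[i, j] <- n_pot[i, j] + 1
        if (length(after)) n_dep[i, j] <- n_dep[i, j] + 1
      }
    }
  }
  W * (1 - W) * (stdp$mu_plus * n_pot - stdp$mu_minus * n_dep)
}

#' Hook pipeline for weight updates
#'
#' Optional transformations applied to the proposed weight change, in the
#' documented order quantize -> programming noise -> add -> clip ->
#' prune mask -> stuck-at-fault mask. Each hook is a pure function on the
#' update matrix.
#'
#' @param quantizer Function mapping the update matrix onto the fixed-point
#'   lattice (see [make_quantizer_hook()]), or `NULL`.
#' @param noise Function adding programming noise to the quantized update
#'   (see [make_prog_noise_hook()]), or `NULL`. Noise is applied only where
#'   an update is actually written (nonzero proposed change).
#' @param prune Online-pruning settings: a [prune_config()] with
#'   `mode = "online"`, or `NULL`. The threshold is re-applied after each
#'   window's update once the warmup has elapsed; pruned synapses stay 0.
#' @return An object of class `update_hooks`.
#' @export
update_hooks <- function(quantizer = NULL, noise = NULL, prune = NULL) {
  structure(list(quantizer = quantizer, noise = noise, prune = prune,
                 images_seen = 0L),
            class = "update_hooks")
}

#' Apply a weight update through the hook pipeline
#'
#' The proposed change passes through the quantizer hook, then the noise
#' hook (on entries with a nonzero proposed change — each such entry is one
#' device write), is added to the weights, and the result is clipped to
#' \[0, 1\]. Pruned synapses stay at 0; stuck-at-fault synapses are
#' re-clamped to their stuck value so faults persist through training.
#'
#' @param W Weight matrix in \[0, 1\].
#' @param delta Proposed weight-change matrix (same shape).
#' @param hooks An [update_hooks()] object or `NULL`.
#' @param prune_mask Logical matrix of already-pruned synapses.
#' @param saf Stuck-at-fault state from [sample_saf_mask()], or `NULL`.
#' @return List with the updated `W`, the (possibly grown) `prune_mask`,
#'   and `n_updates` — the number of synapses written this call.
#' @export
apply_updates <- function(W, delta, hooks = NULL,
                          prune_mask = NULL, saf = NULL) {
  stopifnot(all(dim(W) == dim(delta)))
  prune_mask <- prune_mask %||% matrix(FALSE, nrow(W), ncol(W))
  written <- delta != 0
  d <- delta
  if (!is.null(hooks$quantizer)) d <- hooks$quantizer(d)
  if (!is.null(hooks$noise)) {
    noisy <- hooks$noise(d)
    d[written] <- noisy[written]
  }
  W <- pmin(pmax(W + d, 0), 1)
  if (!is.null(hooks$prune) && hooks$prune$mode == "online" &&
      hooks$images_seen >= hooks$prune$warmup_images) {
    pr <- prune_weights(W, hooks$prune$threshold, mask = prune_mask)
    W <- pr$W
    prune_mask <- pr$mask
  }
  W[prune_mask] <- 0
  if (!is.null(saf)) W <- apply_saf(W, saf)
  list(W = W, prune_mask = prune_mask, n_updates = sum(written))
}
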
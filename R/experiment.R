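#' Per-scheme simulation configuration
#'
#' Bundles the encoder parameters, neuron/synapse/adaptation parameters,
#' STDP learning rates, time step, windows and epoch count for one coding
#' scheme. Defaults are the per-scheme simulation values: LIF time constant
#' 10 ms throughout; firing thresholds 0.6/0.5/0.8/0.4 mV, conductance time
#' constants 30/10/30/30 ms, learning rates (mu-, mu+) of (0.002, 0.02) /
#' (0.0004, 0.09) / (0.006, 0.004) / (0.001, 0.07), and adaptation
#' constants 0.008/0.04/0.008/0.005 mV for rate/TTFS/phase/burst. The
#' default windows are each scheme's optimal training latency (80/20/30/20
#' ms) and inference latency (150/20/30/30 ms), with 4/4/3/3 training
#' epochs. Phase coding steps the clock at 1 ms (one phase per step); the
#' other schemes at 0.5 ms.
#'
#' @param scheme One of `"rate"`, `"ttfs"`, `"phase"`, `"burst"`.
#' @param ... Overrides for any field: `encoder`, `lif`, `syn`, `adapt`,
#'   `stdp`, `coupling`, `dt`, `train_window`, `infer_window`, `epochs`.
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("rate", "ttfs", "phase", "burst"), ...) {
  scheme <- match.arg(scheme)
  d <- switch(scheme,
    rate = list(encoder = rate_params(), lif = lif_params(v_th = 0.6),
                coupling = coupling_params(input_gain = 0.2),
                syn = synapse_params(30),
                adapt = adapt_params(theta_plus = 0.008),
                stdp = stdp_params(mu_plus = 0.02, mu_minus = 0.002),
                dt = 0.5, train_window = 80, infer_window = 150, epochs = 4L),
    ttfs = list(encoder = ttfs_params(), lif = lif_params(v_th = 0.5),
                coupling = coupling_params(input_gain = 0.8),
                syn = synapse_params(10),
                adapt = adapt_params(theta_plus = 0.04),
                stdp = stdp_params(mu_plus = 0.09, mu_minus = 0.0004),
                dt = 0.5, train_window = 20, infer_window = 20, epochs = 4L),
    phase = list(encoder = phase_params(), lif = lif_params(v_th = 0.8),
                 coupling = coupling_params(input_gain = 0.1),
                 syn = synapse_params(30),
                 adapt = adapt_params(theta_plus = 0.008),
                 stdp = stdp_params(mu_plus = 0.004, mu_minus = 0.006),
                 dt = 1, train_window = 30, infer_window = 30, epochs = 3L),
    burst = list(encoder = burst_params(), lif = lif_params(v_th = 0.4),
                 coupling = coupling_params(input_gain = 0.2),
                 syn = synapse_params(30),
                 adapt = adapt_params(theta_plus = 0.005),
                 stdp = stdp_params(mu_plus = 0.07, mu_minus = 0.001),
                 dt = 0.5, train_window = 20, infer_window = 20, epochs = 3L)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(d)))
  if (length(bad)) stop("unknown scheme_config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  d[names(dots)] <- dots
  d$scheme <- scheme
  structure(d, class = "scheme_config")
}

#' Experiment configuration
#'
#' Everything needed for one train-label-infer experiment: the coding
#' scheme, network size, data source, seeds, and any perturbation,
#' compression, or non-ideality settings.
#'
#' @param scheme Coding scheme name, or a full [scheme_config()].
#' @param data A [synthetic_spec()] (the dataset is generated on the fly)
#'   or a list with `train` and `test`, each holding `images`
#'   (`h x w x n` array) and `labels` (integer classes).
#' @param n_exc Number of excitatory neurons.
#' @param epochs Training epochs (0 = evaluate the untrained network).
#' @param seed Master RNG seed for the whole run.
#' @param input_noise Optional list `list(kind =, phase = "train"|"infer"|
#'   "both", ...)` with parameters for [perturb_image()].
#' @param quant_bits Training-time quantization bit width (updates pass
#'   through stochastic rounding), or `NULL`.
#' @param prog_noise_sigma Training-time programming-noise level as a
#'   fraction of the quantization precision (requires `quant_bits`), or
#'   `NULL`.
#' @param saf A [saf_config()] applied before training starts, or `NULL`.
#' @param prune A [prune_config()] (online or post), or `NULL`.
#' @param post_quant_bits Post-training quantization bit width, or `NULL`.
#' @param post_prog_noise_sigma Programming-noise level applied once when
#'   mapping the (post-)quantized weights, as a fraction of the precision
#'   (requires `post_quant_bits`), or `NULL`.
#' @param ... Overrides forwarded to [scheme_config()] when `scheme` is a
#'   name.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scheme = "rate", data = synthetic_spec(),
                              n_exc = 10, epochs = NULL, seed = 1,
                              input_noise = NULL, quant_bits = NULL,
                              prog_noise_sigma = NULL, saf = NULL,
                              prune = NULL, post_quant_bits = NULL,
                              post_prog_noise_sigma = NULL, ...) {
  cfg <- if (inherits(scheme, "scheme_config")) scheme else
    scheme_config(scheme, ...)
  if (!is.null(prog_noise_sigma) && is.null(quant_bits)) {
    stop("`prog_noise_sigma` requires `quant_bits` (the device precision)",
         call. = FALSE)
  }
  if (!is.null(post_prog_noise_sigma) && is.null(post_quant_bits)) {
    stop("`post_prog_noise_sigma` requires `post_quant_bits`", call. = FALSE)
  }
  structure(
    list(scheme_cfg = cfg, data = data, n_exc = as.integer(n_exc),
         epochs = as.integer(epochs %||% cfg$epochs), seed = seed,
         input_noise = input_noise, quant_bits = quant_bits,
         prog_noise_sigma = prog_noise_sigma, saf = saf, prune = prune,
         post_quant_bits = post_quant_bits,
         post_prog_noise_sigma = post_prog_noise_sigma),
    class = "experiment_config"
  )
}

get_image <- function(images, i) images[, , i]

maybe_perturb <- function(img, noise, phase) {
  if (is.null(noise)) return(img)
  if (!(noise$phase %||% "both") %in% c(phase, "both") &&
      !identical(noise$phase, phase)) return(img)
  args <- noise[setdiff(names(noise), c("kind", "phase"))]
  do.call(perturb_image, c(list(img = img, kind = noise$kind), args))
}

# one pass without plasticity; returns per-image neuron counts + totals
evaluation_pass <- function(images, cfg, topo, state, noise = NULL,
                            phase = "infer") {
  n <- dim(images)[3]
  counts <- matrix(0, n, topo$n_exc)
  spikes_in <- 0; spikes_out <- 0; sops <- 0
  for (i in seq_len(n)) {
    img <- maybe_perturb(get_image(images, i), noise, phase)
    res <- run_window(img, cfg, topo, state, mode = "infer")
    counts[i, ] <- res$trace$per_neuron_counts
    spikes_in <- spikes_in + res$trace$input_spikes
    spikes_out <- spikes_out + res$trace$output_spikes
    sops <- sops + res$trace$sops
  }
  list(counts = counts, spikes_in = spikes_in, spikes_out = spikes_out,
       sops = sops)
}

#' Run a full train-label-infer experiment
#'
#' Executes the experiment described by an [experiment_config()]: optional
#' input perturbation, STDP training epochs (with any quantization,
#' programming-noise, stuck-at-fault, and pruning hooks attached), a
#' labeling pass over the training set after each epoch, an inference pass
#' over the test set, and optional post-training compression/noise mapping
#' followed by a final evaluation. Fully deterministic given `seed`.
#'
#' @param config An [experiment_config()].
#' @return An object of class `snn_experiment`: list with `metrics` (one
#'   tibble row per evaluation: epoch, accuracy, spike/SOP totals,
#'   latencies, connectivity), `topo`, `state`, `labels`, `predictions`,
#'   and `config`. Use [tidy()]/[glance()]/[autoplot()] on it.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config$scheme_cfg
  set.seed(config$seed)

  data <- if (inherits(config$data, "synthetic_spec")) {
    generate_synthetic(config$data)
  } else config$data
  train <- data$train; test <- data$test
  n_px <- prod(dim(train$images)[1:2])
  classes <- sort(unique(c(train$labels, test$labels)))

  topo <- build_topology(n_px, config$n_exc, cfg$coupling)
  if (!is.null(config$quant_bits)) {
    # b-bit weight storage holds the initial weights too, not just updates
    topo$W <- quantize_weights(topo$W, quant_config(config$quant_bits))
  }
  if (!is.null(config$saf)) {
    topo$saf <- sample_saf_mask(dim(topo$W), config$saf)
    topo$W <- apply_saf(topo$W, topo$saf)
  }
  eps <- if (!is.null(config$quant_bits)) quant_config(config$quant_bits)$epsilon
  hooks <- update_hooks(
    quantizer = if (!is.null(config$quant_bits))
      make_quantizer_hook(quant_config(config$quant_bits)),
    noise = if (!is.null(config$prog_noise_sigma))
      make_prog_noise_hook(prog_noise_config(config$prog_noise_sigma, eps)),
    prune = if (!is.null(config$prune) && config$prune$mode == "online")
      config$prune
  )
  state <- network_state(topo, cfg$lif)

  count_matrix <- function(counts, labels) {
    t(vapply(seq_len(ncol(counts)), function(j)
      vapply(classes, function(k) sum(counts[labels == k, j]), numeric(1)),
      numeric(length(classes))))
  }
  evaluate <- function(epoch, train_stats) {
    lab <- evaluation_pass(train$images, cfg, topo, state,
                           config$input_noise, "train")
    labels <- assign_labels(count_matrix(lab$counts, train$labels), classes)
    inf <- evaluation_pass(test$images, cfg, topo, state,
                           config$input_noise, "infer")
    preds <- apply(inf$counts, 1, predict_class, labels = labels)
    row <- tibble::tibble(
      epoch = epoch,
      accuracy = accuracy(preds, test$labels),
      train_input_spikes = train_stats$spikes_in,
      train_output_spikes = train_stats$spikes_out,
      train_sops = train_stats$sops,
      infer_input_spikes = inf$spikes_in,
      infer_output_spikes = inf$spikes_out,
      infer_sops = inf$sops,
      train_window = cfg$train_window,
      infer_window = cfg$infer_window,
      connectivity = connectivity(topo$prune_mask)
    )
    list(row = row, labels = labels, preds = preds)
  }

  metrics <- list()
  last_eval <- NULL
  record <- function(ev) {
    metrics[[length(metrics) + 1]] <<- ev$row
    last_eval <<- ev
  }
  images_seen <- 0L
  if (config$epochs == 0) {
    record(evaluate(0L, list(spikes_in = 0, spikes_out = 0, sops = 0)))
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(dim(train$images)[3])
    st <- list(spikes_in = 0, spikes_out = 0, sops = 0)
    for (i in ord) {
      img <- maybe_perturb(get_image(train$images, i), config$input_noise,
                           "train")
      hooks$images_seen <- images_seen
      res <- run_window(img, cfg, topo, state, mode = "train", hooks = hooks)
      topo <- res$topo; state <- res$state
      st$spikes_in <- st$spikes_in + res$trace$input_spikes
      st$spikes_out <- st$spikes_out + res$trace$output_spikes
      st$sops <- st$sops + res$trace$sops
      images_seen <- images_seen + 1L
    }
    record(evaluate(epoch, st))
  }

  # post-training transforms: prune / quantize / programming-noise mapping
  post <- !is.null(config$post_quant_bits) ||
    (!is.null(config$prune) && config$prune$mode == "post")
  if (post) {
    if (!is.null(config$prune) && config$prune$mode == "post") {
      pr <- prune_weights(topo$W, config$prune$threshold,
                          mask = topo$prune_mask)
      topo$W <- pr$W; topo$prune_mask <- pr$mask
    }
    if (!is.null(config$post_quant_bits)) {
      qc <- quant_config(config$post_quant_bits)
      topo$W <- quantize_weights(topo$W, qc)
      if (!is.null(config$post_prog_noise_sigma)) {
        pn <- prog_noise_config(config$post_prog_noise_sigma, qc$epsilon)
        topo$W <- pmin(pmax(programming_noise(topo$W, pn), 0), 1)
      }
      topo$W[topo$prune_mask] <- 0
      if (!is.null(topo$saf)) topo$W <- apply_saf(topo$W, topo$saf)
    }
    record(evaluate(config$epochs + 1L,
                    list(spikes_in = 0, spikes_out = 0, sops = 0)))
  }

  structure(
    list(metrics = dplyr::bind_rows(metrics), topo = topo, state = state,
         labels = last_eval$labels, predictions = last_eval$preds,
         config = config),
    class = "snn_experiment"
  )
}

#' @export
print.snn_experiment <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "<snn_experiment> %s coding, %d exc neurons, %d epoch(s): accuracy %.1f%%, connectivity %.1f%%\n",
    x$config$scheme_cfg$scheme, x$config$n_exc, x$config$epochs,
    m$accuracy, m$connectivity))
  invisible(x)
}

#' Compare coding schemes on one dataset
#'
#' Runs [run_experiment()] for each scheme on the same data and seed, and
#' summarizes accuracy, effective latency (training window times epochs,
#' plus the inference window), spike and SOP totals (training + inference
#' sums), and the [compute_fom()] figure of merit normalized over the
#' compared set.
#'
#' @param schemes Character vector of scheme names.
#' @param data As in [experiment_config()].
#' @param n_exc Number of excitatory neurons.
#' @param epochs Training epochs (`NULL` = per-scheme defaults).
#' @param seed Master seed (shared across schemes).
#' @param ... Further arguments passed to [experiment_config()].
#' @return An object of class `snn_comparison`: list with `summary` (one
#'   tibble row per scheme incl. `fom`), `radar` (min-max normalized
#'   goodness per scheme and metric), and `experiments`.
#' @export
run_comparison <- function(schemes = c("rate", "ttfs", "phase", "burst"),
                           data = synthetic_spec(), n_exc = 10,
                           epochs = NULL, seed = 1, ...) {
  experiments <- lapply(schemes, function(s) {
    run_experiment(experiment_config(scheme = s, data = data, n_exc = n_exc,
                                     epochs = epochs, seed = seed, ...))
  })
  names(experiments) <- schemes
  summary <- dplyr::bind_rows(lapply(experiments, glance.snn_experiment))
  summary <- compute_fom(summary)
  radar <- summary |>
    dplyr::transmute(
      scheme = .data$scheme,
      accuracy = .data$accuracy / max(.data$accuracy),
      latency = minmax_normalize(.data$latency),
      spikes = minmax_normalize(.data$spikes),
      sops = minmax_normalize(.data$sops)
    ) |>
    tidyr::pivot_longer(-"scheme", names_to = "metric", values_to = "score")
  structure(list(summary = summary, radar = radar, experiments = experiments),
            class = "snn_comparison")
}

#' @export
print.snn_comparison <- function(x, ...) {
  cat("<snn_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Write comparison results to CSV
#'
#' One row per scheme with accuracy, latency, spikes, SOPs, and FOM;
#' optionally also the min-max normalized radar table.
#'
#' @param comparison An `snn_comparison`.
#' @param path Output CSV path for the summary.
#' @param radar_path Optional path for the normalized radar CSV.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path, radar_path = NULL) {
  utils::write.csv(comparison$summary, path, row.names = FALSE)
  if (!is.null(radar_path)) {
    utils::write.csv(comparison$radar, radar_path, row.names = FALSE)
  }
  invisible(path)
}
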
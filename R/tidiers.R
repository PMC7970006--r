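#' Tidy an experiment's per-epoch metrics
#'
#' @param x An `snn_experiment`.
#' @param ... Unused.
#' @return The per-evaluation metrics tibble (one row per epoch plus any
#'   post-training evaluation).
#' @method tidy snn_experiment
#' @export
tidy.snn_experiment <- function(x, ...) x$metrics

#' One-row experiment summary
#'
#' Final accuracy plus the totals entering the figure of merit: effective
#' latency (training window times epochs plus the inference window), and
#' training + inference spike and SOP sums.
#'
#' @param x An `snn_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with columns `scheme`, `accuracy`, `latency`,
#'   `spikes`, `sops`, `connectivity`, `epochs`.
#' @method glance snn_experiment
#' @export
glance.snn_experiment <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  tibble::tibble(
    scheme = x$config$scheme_cfg$scheme,
    accuracy = last$accuracy,
    latency = last$train_window * x$config$epochs + last$infer_window,
    spikes = sum(m$train_input_spikes + m$train_output_spikes) +
      last$infer_input_spikes + last$infer_output_spikes,
    sops = sum(m$train_sops) + last$infer_sops,
    connectivity = last$connectivity,
    epochs = x$config$epochs
  )
}

#' @method tidy snn_comparison
#' @export
tidy.snn_comparison <- function(x, ...) x$summary

#' Plot learning curves
#'
#' Accuracy against training epoch for one experiment.
#'
#' @param object An `snn_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snn_experiment
#' @export
autoplot.snn_experiment <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$epoch, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training epoch", y = "test accuracy (%)",
                  title = sprintf("%s coding",
                                  object$config$scheme_cfg$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a spike raster
#'
#' Event plot of a `spike_raster`: one point per spike, shaded by its
#' decoding weight.
#'
#' @param object A `spike_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) {
  ev <- raster_events(object)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time_ms, y = .data$neuron,
                                   alpha = .data$weight)) +
    ggplot2::geom_point(shape = "|", size = 2, show.legend = FALSE) +
    ggplot2::labs(x = "time (ms)", y = "input neuron",
                  title = sprintf("%s coding", object$scheme)) +
    ggplot2::theme_minimal()
}

#' Radar-style comparison plot
#'
#' Min-max normalized goodness per scheme on each compared metric (larger
#' is better), drawn on polar coordinates.
#'
#' @param object An `snn_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snn_comparison
#' @export
autoplot.snn_comparison <- function(object, ...) {
  ggplot2::ggplot(object$radar,
                  ggplot2::aes(x = .data$metric, y = .data$score,
                               group = .data$scheme,
                               colour = .data$scheme)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "normalized score (1 = best)") +
    ggplot2::theme_minimal()
}

#' Plot learned receptive fields
#'
#' Input weights of each excitatory neuron reshaped to the image grid.
#'
#' @param topo An `snn_topology`.
#' @param image_size Pixels per side of the input image.
#' @return A ggplot object.
#' @export
plot_receptive_fields <- function(topo, image_size) {
  stopifnot(topo$n_input == image_size^2)
  df <- purrr::map_dfr(seq_len(topo$n_exc), function(j) {
    tibble::tibble(
      neuron = j,
      row = rep(seq_len(image_size), times = image_size),
      col = rep(seq_len(image_size), each = image_size),
      w = topo$W[, j]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~neuron) +
    ggplot2::labs(fill = "weight") +
    ggplot2::theme_minimal()
}
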
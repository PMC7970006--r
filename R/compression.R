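#' Fixed-point quantization settings
#'
#' Weights live in \[0, 1\] and are represented as unsigned fixed point with
#' `bits` fractional bits, so the lattice precision is `epsilon = 2^-bits`.
#'
#' @param bits Bit width (>= 1).
#' @return An object of class `quant_config` with fields `bits`, `epsilon`.
#' @export
quant_config <- function(bits) {
  stopifnot(bits >= 1)
  structure(list(bits = as.integer(bits), epsilon = 2^-bits),
            class = "quant_config")
}

#' Stochastic rounding
#'
#' Rounds `x` onto the `epsilon` lattice with probability proportional to
#' proximity: the lower lattice point `floor(x / epsilon) * epsilon` with
#' probability `1 - (x - lower) / epsilon`, the upper one otherwise.
#' Unbiased (`E[SR(x)] = x`), with support on the two neighboring lattice
#' points only — so a small weight update has a nonzero probability of not
#' being rounded to 0.
#'
#' @param x Numeric vector/matrix.
#' @param epsilon Lattice precision (> 0).
#' @return `x` rounded onto the lattice, same shape.
#' @export
stochastic_round <- function(x, epsilon) {
  stopifnot(epsilon > 0)
  lower <- floor(x / epsilon) * epsilon
  frac <- (x - lower) / epsilon
  up <- stats::runif(length(x)) < frac
  out <- lower + up * epsilon
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Stochastically quantize a weight matrix
#'
#' Every entry is stochastically rounded to the fixed-point lattice and the
#' result clipped to \[0, 1\]. Used post-training to map trained weights
#' onto limited-precision storage; during training the same rounding is
#' attached to each weight update via [make_quantizer_hook()].
#'
#' @param W Weight matrix in \[0, 1\].
#' @param cfg A [quant_config()].
#' @return Quantized weight matrix.
#' @export
quantize_weights <- function(W, cfg) {
  pmin(pmax(stochastic_round(W, cfg$epsilon), 0), 1)
}

#' Quantizer hook for training-time quantization
#'
#' Returns a function that stochastically rounds each proposed weight
#' update onto the `epsilon` lattice, for use in [update_hooks()].
#'
#' @param cfg A [quant_config()].
#' @return Function of one matrix argument.
#' @export
make_quantizer_hook <- function(cfg) {
  force(cfg)
  function(delta) stochastic_round(delta, cfg$epsilon)
}

#' Pruning settings
#'
#' @param threshold Weight cutoff in \[0, 1\]: synapses with weight below it
#'   are removed and frozen at 0.
#' @param mode `"online"` (threshold re-applied after each image window
#'   during training, once `warmup_images` images have been presented) or
#'   `"post"` (applied once to the trained weights before inference).
#' @param warmup_images Images presented before online pruning starts.
#' @return An object of class `prune_config`.
#' @export
prune_config <- function(threshold, mode = c("post", "online"),
                         warmup_images = 0) {
  if (threshold < 0 || threshold > 1) {
    stop("pruning threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(list(threshold = threshold, mode = match.arg(mode),
                 warmup_images = as.integer(warmup_images)),
            class = "prune_config")
}

#' Prune small weights
#'
#' Entries with weight below the threshold are set to 0 and recorded in the
#' mask; once masked, a synapse never revives. An existing mask can be
#' passed to accumulate online-pruning decisions across windows.
#'
#' @param W Weight matrix.
#' @param threshold Cutoff in \[0, 1\].
#' @param mask Optional logical matrix of already-pruned synapses.
#' @return List with pruned `W` and the updated logical `mask`.
#' @export
prune_weights <- function(W, threshold, mask = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("pruning threshold must lie in [0, 1]", call. = FALSE)
  }
  mask <- (mask %||% matrix(FALSE, nrow(W), ncol(W))) | (abs(W) < threshold)
  W[mask] <- 0
  list(W = W, mask = mask)
}

#' Network connectivity after pruning
#'
#' Percentage of unpruned synapses over the total.
#'
#' @param mask Logical matrix, `TRUE` marking pruned synapses.
#' @return Connectivity in percent.
#' @export
connectivity <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  100 * sum(!mask) / length(mask)
}
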
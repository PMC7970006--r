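#' Assign class labels to excitatory neurons
#'
#' Each neuron is labeled with the class for which it fired the most spikes
#' over a labeling pass of the training set. Ties (including all-silent
#' neurons) resolve to the lowest class index, with a warning for silent
#' neurons.
#'
#' @param count_matrix Numeric matrix (`n_neurons` x `n_classes`) of summed
#'   spike counts; column `k` corresponds to class `classes[k]`.
#' @param classes Class identifiers for the columns (default `0:(K-1)`).
#' @return An object of class `neuron_labels`: list with `label` (class id
#'   per neuron) and `groups` (class id -> neuron indices).
#' @export
assign_labels <- function(count_matrix, classes = NULL) {
  stopifnot(all(count_matrix >= 0))
  classes <- classes %||% (seq_len(ncol(count_matrix)) - 1L)
  silent <- rowSums(count_matrix) == 0
  if (any(silent)) {
    warning(sum(silent), " neuron(s) never fired during labeling; ",
            "assigned the lowest class by the tie rule", call. = FALSE)
  }
  pick <- apply(count_matrix, 1, which.max)  # first max = lowest class index
  label <- classes[pick]
  structure(
    list(label = label,
         groups = split(seq_along(label), factor(label, levels = classes))),
    class = "neuron_labels"
  )
}

#' Predict the class of one inference window
#'
#' The predicted class is the neuron group with the highest mean spike
#' count over the window; ties resolve to the lowest class index. Empty
#' groups are excluded (with a warning).
#'
#' @param per_neuron_counts Spike count per excitatory neuron.
#' @param labels A `neuron_labels` object from [assign_labels()].
#' @return The predicted class id.
#' @export
predict_class <- function(per_neuron_counts, labels) {
  groups <- labels$groups
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(groups)[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]
  }
  means <- vapply(groups, function(id) mean(per_neuron_counts[id]), numeric(1))
  cls <- names(groups)[which.max(means)]   # first max = lowest class
  out <- utils::type.convert(cls, as.is = TRUE)
  out
}

#' Classification accuracy
#'
#' @param preds,truths Equal-length vectors of predicted and true classes.
#' @return Accuracy in percent.
#' @export
accuracy <- function(preds, truths) {
  if (length(preds) != length(truths)) {
    stop("`preds` and `truths` must have equal length", call. = FALSE)
  }
  if (length(preds) == 0) stop("no predictions", call. = FALSE)
  100 * mean(preds == truths)
}

#' Figure of merit
#'
#' `FOM = accuracy / (latency * spikes * SOPs)`, with every quantity first
#' normalized by its maximum over the compared configuration set, so that
#' a configuration attaining all four maxima scores exactly 1. Totals are
#' training + inference sums. Halving any normalized cost doubles the FOM.
#'
#' @param df Data frame with one row per configuration and columns
#'   `accuracy` (percent), `latency` (ms), `spikes`, `sops`.
#' @param maxima Optional named list overriding the normalization maxima
#'   (`accuracy`, `latency`, `spikes`, `sops`); defaults to the column
#'   maxima of `df`.
#' @return `df` with an added `fom` column, as a tibble.
#' @export
compute_fom <- function(df, maxima = NULL) {
  need <- c("accuracy", "latency", "spikes", "sops")
  stopifnot(all(need %in% names(df)))
  mx <- lapply(need, function(v) maxima[[v]] %||% max(df[[v]]))
  names(mx) <- need
  if (any(unlist(mx) <= 0)) stop("normalization maxima must be positive",
                                 call. = FALSE)
  denom <- (df$latency / mx$latency) * (df$spikes / mx$spikes) *
    (df$sops / mx$sops)
  if (any(denom == 0)) stop("zero denominator in FOM", call. = FALSE)
  tibble::as_tibble(dplyr::mutate(df, fom = (accuracy / mx$accuracy) / denom))
}

#' Min-max normalization of a loss metric
#'
#' `(x_max - x_i) / (x_max - x_min)`: the worst (largest-loss) scheme maps
#' to 0, the best to 1, linearly in between — the scale used on each axis
#' of the cross-scheme radar comparison. A degenerate range returns 0.5
#' everywhere with a warning.
#'
#' @param x Numeric vector of per-scheme losses (or costs).
#' @return Normalized values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("degenerate range in min-max normalization; returning 0.5",
            call. = FALSE)
    return(rep(0.5, length(x)))
  }
  (rng[2] - x) / (rng[2] - rng[1])
}
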
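#' deSNN classifier parameters
#'
#' The dynamic evolving SNN output layer grows one output neuron per
#' training sample. Connections from reservoir neurons are initialised by
#' the rank-order rule `W_i = mod^order(i)` (order = 0-based rank of
#' neuron i's first spike within the sample) and then adjusted by `drift`
#' for every subsequent spike. Classification either compares rank-order
#' weight vectors by Euclidean distance (`"weight_similarity"`, the
#' standard deSNN decision rule) or picks the output neuron with maximal
#' rank-order potential `PSP = sum mod^order(i) * W_i` computed from the
#' test sample's spike orders (`"psp_spiking"`).
#'
#' @param mod rank-order modulation factor, in (0, 1).
#' @param drift weight increment per repeated spike (>= 0).
#' @param drift_decay also decrease weights by `drift` for every silent
#'   step after a neuron's first spike.
#' @param mode `"weight_similarity"` or `"psp_spiking"`.
#' @return A `desnn_config` object.
#' @export
desnn_config <- function(mod = 0.4, drift = 0.005, drift_decay = FALSE,
                         mode = c("weight_similarity", "psp_spiking")) {
  if (mod <= 0 || mod >= 1) stop_input("`mod` must be in (0, 1)")
  if (drift < 0) stop_input("`drift` must be >= 0")
  structure(list(mod = mod, drift = drift, drift_decay = isTRUE(drift_decay),
                 mode = match.arg(mode)),
            class = "desnn_config")
}

# First-spike time (NA if silent) and spike count per neuron from a
# (step, neuron) spike record.
first_spikes <- function(spikes, n_neurons) {
  first <- rep(NA_integer_, n_neurons)
  count <- integer(n_neurons)
  if (nrow(spikes) > 0) {
    ord <- order(spikes[, "step"], spikes[, "neuron"])
    st <- spikes[ord, "step"]
    ne <- spikes[ord, "neuron"]
    f <- !duplicated(ne)
    first[ne[f]] <- st[f]
    tab <- tabulate(ne, nbins = n_neurons)
    count <- tab
  }
  list(first = first, count = count)
}

# 0-based global rank of each neuron's first spike (ties by neuron index);
# NA for silent neurons.
spike_orders <- function(spikes, n_neurons) {
  fs <- first_spikes(spikes, n_neurons)
  ord <- rep(NA_integer_, n_neurons)
  spiked <- which(!is.na(fs$first))
  if (length(spiked) > 0) {
    r <- spiked[order(fs$first[spiked], spiked)]
    ord[r] <- seq_along(r) - 1L
  }
  ord
}

#' Train one output neuron by the rank-order rule
#'
#' For each reservoir neuron that spiked, the initial weight is
#' `mod^order` at its first spike; every later spike of the same neuron
#' adds `drift`. With `drift_decay` enabled, the weight also decreases by
#' `drift` for each step after the first spike in which the neuron stayed
#' silent. Neurons that never spike keep weight 0. An empty record yields
#' an all-zero neuron flagged by the `empty` attribute.
#'
#' @param record a [run_epoch()] result or a (step, neuron) spike matrix.
#' @param n_neurons reservoir size.
#' @param cfg a [desnn_config()].
#' @param label class label attached to the neuron.
#' @param n_steps sample length in steps (needed for `drift_decay`).
#' @return An `output_neuron`: list with `label`, `weights` and `order`.
#' @export
ro_train_output <- function(record, n_neurons, cfg = desnn_config(),
                            label = NA_character_, n_steps = NULL) {
  spikes <- if (is.list(record) && !is.null(record$spikes)) record$spikes else record
  fs <- first_spikes(spikes, n_neurons)
  ord <- spike_orders(spikes, n_neurons)
  w <- numeric(n_neurons)
  spiked <- which(!is.na(ord))
  w[spiked] <- cfg$mod^ord[spiked] + cfg$drift * (fs$count[spiked] - 1L)
  if (cfg$drift_decay) {
    if (is.null(n_steps)) stop_input("`n_steps` is required when drift_decay is on")
    silent <- (n_steps - fs$first[spiked]) - (fs$count[spiked] - 1L)
    w[spiked] <- w[spiked] - cfg$drift * silent
  }
  out <- list(label = label, weights = w, order = ord)
  attr(out, "empty") <- length(spiked) == 0
  class(out) <- "output_neuron"
  out
}

#' Train a deSNN output layer
#'
#' Evolves one rank-order output neuron per training sample.
#'
#' @param records list of [run_epoch()] results (or spike matrices), one
#'   per training sample.
#' @param labels class label per sample.
#' @param n_neurons reservoir size.
#' @param cfg a [desnn_config()].
#' @param n_steps sample length in steps (for `drift_decay`).
#' @return A `desnn_layer`: weight matrix (samples x neurons), per-sample
#'   labels, per-sample spike orders and the config.
#' @export
desnn_train <- function(records, labels, n_neurons, cfg = desnn_config(),
                        n_steps = NULL) {
  if (length(records) != length(labels)) stop_input("one label per record required")
  if (length(records) == 0) stop_input("no training records")
  neurons <- mapply(function(r, l) ro_train_output(r, n_neurons, cfg, l, n_steps),
                    records, labels, SIMPLIFY = FALSE)
  W <- do.call(rbind, lapply(neurons, `[[`, "weights"))
  orders <- do.call(rbind, lapply(neurons, `[[`, "order"))
  structure(list(weights = W, labels = as.character(labels), orders = orders,
                 cfg = cfg, n_neurons = n_neurons, n_steps = n_steps),
            class = "desnn_layer")
}

#' Rank-order potential of an output neuron
#'
#' `PSP(j) = sum over spiking inputs i of mod^order(i) * W_ij`, with the
#' spike orders taken from the test sample.
#'
#' @param weights output neuron weight vector (length = reservoir size).
#' @param test_order 0-based first-spike orders of the test sample
#'   (NA = silent), as from an [ro_train_output()] `order` field.
#' @param cfg a [desnn_config()].
#' @return The potential (0 when nothing spiked).
#' @export
desnn_psp <- function(weights, test_order, cfg = desnn_config()) {
  spiked <- which(!is.na(test_order))
  if (length(spiked) == 0) return(0)
  sum(cfg$mod^test_order[spiked] * weights[spiked])
}

#' Classify a reservoir response with a trained deSNN layer
#'
#' In `weight_similarity` mode a virtual output neuron is trained from the
#' test record and the class of the nearest trained neuron (Euclidean
#' distance between weight vectors) is predicted. In `psp_spiking` mode
#' the class of the trained neuron with maximal rank-order potential is
#' predicted. Ties are broken deterministically by the lowest neuron
#' index.
#'
#' @param layer a [desnn_train()] result.
#' @param record test-sample [run_epoch()] result or spike matrix.
#' @param cfg a [desnn_config()]; defaults to the layer's config.
#' @return List with `class`, `scores` (per trained neuron: distance or
#'   PSP), and `best` (index of the winning neuron).
#' @export
desnn_classify <- function(layer, record, cfg = layer$cfg) {
  stopifnot(inherits(layer, "desnn_layer"))
  if (nrow(layer$weights) == 0) stop_input("no trained output neurons")
  test <- ro_train_output(record, layer$n_neurons, cfg, n_steps = layer$n_steps)
  if (cfg$mode == "weight_similarity") {
    d2 <- rowSums(sweep(layer$weights, 2, test$weights)^2)
    best <- which.min(d2) # which.min takes the first (lowest index) on ties
    scores <- sqrt(d2)
  } else {
    psp <- apply(layer$weights, 1, desnn_psp, test_order = test$order, cfg = cfg)
    best <- which.max(psp)
    scores <- psp
  }
  list(class = layer$labels[best], scores = scores, best = best)
}
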
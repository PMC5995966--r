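#' Leaky integrate-and-fire neuron parameters
#'
#' Each neuron accumulates a post-synaptic potential (PSP) from incoming
#' weighted spikes, leaks multiplicatively between steps
#' (`P <- P * exp(-dt / tau_leak_ms)` with `dt` one sample period), fires
#' when the PSP reaches `theta_fire`, then resets to `reset` and stays
#' refractory for `refractory_steps` simulation steps.
#'
#' @param theta_fire firing threshold (potential units).
#' @param tau_leak_ms leak time constant in ms.
#' @param refractory_steps refractory period in steps.
#' @param reset potential after firing.
#' @return A `lif_config` object.
#' @export
lif_config <- function(theta_fire = 0.5, tau_leak_ms = 10,
                       refractory_steps = 1L, reset = 0) {
  if (theta_fire <= 0) stop_input("`theta_fire` must be positive")
  if (tau_leak_ms <= 0) stop_input("`tau_leak_ms` must be positive")
  refractory_steps <- check_count(refractory_steps, "refractory_steps", min = 0L)
  if (reset != 0) stop_input("only `reset = 0` is supported")
  structure(list(theta_fire = theta_fire, tau_leak_ms = tau_leak_ms,
                 refractory_steps = refractory_steps, reset = reset),
            class = "lif_config")
}

#' Spike-time-dependent plasticity parameters
#'
#' The weight change for a pre/post spike pair separated by
#' `dt = t_pre - t_post` is `rate * A+ * exp(dt / tau+)` for `dt < 0`
#' (pre before post: potentiation) and `-rate * A- * exp(-dt / tau-)` for
#' `dt >= 0` (depression), with nearest-spike pairing and weights clipped
#' to `[w_min, w_max]`. `rate` is the global STDP learning rate.
#'
#' @param rate global learning-rate multiplier.
#' @param a_plus,a_minus maximum adjustments near `dt = 0`.
#' @param tau_plus_ms,tau_minus_ms time constants in ms.
#' @param w_min,w_max weight bounds.
#' @return An `stdp_config` object.
#' @export
stdp_config <- function(rate = 0.01, a_plus = 1, a_minus = 1,
                        tau_plus_ms = 10, tau_minus_ms = 10,
                        w_min = -1, w_max = 1) {
  if (rate < 0) stop_input("`rate` must be >= 0")
  if (a_plus < 0 || a_minus < 0) stop_input("`a_plus`/`a_minus` must be >= 0")
  if (tau_plus_ms <= 0 || tau_minus_ms <= 0) stop_input("STDP time constants must be positive")
  if (w_min > w_max) stop_input("`w_min` must be <= `w_max`")
  structure(list(rate = rate, a_plus = a_plus, a_minus = a_minus,
                 tau_plus_ms = tau_plus_ms, tau_minus_ms = tau_minus_ms,
                 w_min = w_min, w_max = w_max),
            class = "stdp_config")
}

#' STDP weight change for a spike-time difference
#'
#' @param dt_ms signed time difference `t_pre - t_post` in ms (vectorised).
#' @param cfg an [stdp_config()].
#' @return Weight change(s); positive for `dt_ms < 0`, negative otherwise.
#' @export
stdp_delta <- function(dt_ms, cfg = stdp_config()) {
  if (any(!is.finite(dt_ms))) stop_input("`dt_ms` must be finite")
  ifelse(dt_ms < 0,
         cfg$rate * cfg$a_plus * exp(dt_ms / cfg$tau_plus_ms),
         -cfg$rate * cfg$a_minus * exp(-dt_ms / cfg$tau_minus_ms))
}

#' Assemble a reservoir model
#'
#' Binds an atlas, a synapse set and LIF parameters into a runnable model.
#' Negative (-1) input spikes are delivered as negative potential
#' increments to the channel's input neuron (`negative_input = "signed"`,
#' the default) or, with `"separate_line"`, as positive increments to a
#' dedicated second input neuron per channel (the next-nearest lattice
#' neuron to the electrode).
#'
#' @param atlas a [build_atlas()] result.
#' @param synapses a `synapse_set` from [init_small_world()].
#' @param lif a [lif_config()].
#' @param fs sampling rate (Hz); one simulation step per sample.
#' @param negative_input `"signed"` or `"separate_line"`.
#' @return A `reservoir_model` object.
#' @export
reservoir_model <- function(atlas, synapses, lif = lif_config(), fs = 256,
                            negative_input = c("signed", "separate_line")) {
  stopifnot(inherits(atlas, "neuron_atlas"))
  negative_input <- match.arg(negative_input)
  input_map <- setNames(atlas$id[atlas$is_input], atlas$channel[atlas$is_input])
  neg_map <- NULL
  if (negative_input == "separate_line") {
    montage_rows <- which(atlas$is_input)
    neg_map <- setNames(integer(length(montage_rows)),
                        atlas$channel[montage_rows])
    taken <- atlas$id[montage_rows]
    for (k in seq_along(montage_rows)) {
      i <- montage_rows[k]
      d <- (atlas$x - atlas$x[i])^2 + (atlas$y - atlas$y[i])^2 +
        (atlas$z - atlas$z[i])^2
      ord <- order(d)
      j <- ord[!(atlas$id[ord] %in% c(taken, neg_map))][1]
      if (is.na(j)) stop_input("no free neuron for the negative input line of %s",
                               atlas$channel[i])
      neg_map[k] <- atlas$id[j]
    }
  }
  structure(list(atlas = atlas, synapses = synapses, lif = lif, fs = fs,
                 n_neurons = nrow(atlas), input_map = input_map,
                 neg_input_map = neg_map, negative_input = negative_input),
            class = "reservoir_model")
}

#' @export
print.reservoir_model <- function(x, ...) {
  cat(sprintf("<reservoir_model> %d neurons, %d synapses, %d input channels @ %g Hz\n",
              x$n_neurons, nrow(x$synapses), length(x$input_map), x$fs))
  invisible(x)
}

# Convert a per-epoch spike table (channel, sample_index, polarity) into
# input events (step, neuron, amplitude), sorted by step.
input_events <- function(model, spikes, input_gain = 1) {
  if (nrow(spikes) == 0) {
    return(data.frame(step = integer(0), neuron = integer(0), amp = numeric(0)))
  }
  unknown <- setdiff(unique(spikes$channel), names(model$input_map))
  if (length(unknown) > 0) {
    stop_input("spike channels not mapped to input neurons: %s",
               paste(unknown, collapse = ", "))
  }
  if (model$negative_input == "separate_line") {
    neg <- spikes$polarity < 0
    neuron <- ifelse(neg, model$neg_input_map[spikes$channel],
                     model$input_map[spikes$channel])
    amp <- rep(input_gain, nrow(spikes))
  } else {
    neuron <- model$input_map[spikes$channel]
    amp <- spikes$polarity * input_gain
  }
  ev <- data.frame(step = as.integer(spikes$sample_index),
                   neuron = as.integer(neuron), amp = amp)
  ev[order(ev$step), , drop = FALSE]
}

#' Simulate one epoch of reservoir activity
#'
#' Drives the reservoir with one epoch's input spike trains for `n_steps`
#' simulation steps (one step per EEG sample), optionally adapting the
#' synapses by STDP, and records which neurons fired in each snapshot
#' frame of `frame_ms` milliseconds.
#'
#' @param model a [reservoir_model()].
#' @param spikes per-epoch spike table (`channel`, `sample_index`,
#'   `polarity`), e.g. one element of a [encode_recording()] result.
#' @param n_steps number of simulation steps (epoch length in samples).
#' @param stdp an [stdp_config()].
#' @param learn apply STDP (`TRUE`) or run read-only (`FALSE`).
#' @param frame_ms snapshot frame length in ms.
#' @param input_gain potential increment per input spike.
#' @return List with `model` (weights updated when `learn = TRUE`),
#'   `spikes` (matrix with columns `step`, `neuron`), `counts` (per-neuron
#'   spike counts) and `trajectory` (a `snapshot_trajectory`).
#' @export
run_epoch <- function(model, spikes, n_steps, stdp = stdp_config(),
                      learn = TRUE, frame_ms = 50, input_gain = 1) {
  stopifnot(inherits(model, "reservoir_model"))
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  if (nrow(spikes) > 0 && max(spikes$sample_index) > n_steps) {
    stop_input("input spike index beyond epoch length")
  }
  ev <- input_events(model, spikes, input_gain)
  step_ms <- 1000 / model$fs
  syn <- model$synapses
  res <- lif_stdp_run_cpp(
    n_neurons = model$n_neurons,
    pre = as.integer(syn$pre) - 1L, post = as.integer(syn$post) - 1L,
    w0 = syn$weight,
    ev_step = ev$step, ev_neuron = ev$neuron - 1L, ev_amp = ev$amp,
    n_steps = n_steps,
    theta_fire = model$lif$theta_fire,
    decay = exp(-step_ms / model$lif$tau_leak_ms),
    refractory = model$lif$refractory_steps,
    learn = isTRUE(learn), rate = stdp$rate,
    a_plus = stdp$a_plus, a_minus = stdp$a_minus,
    tau_plus = stdp$tau_plus_ms / step_ms,
    tau_minus = stdp$tau_minus_ms / step_ms,
    w_min = stdp$w_min, w_max = stdp$w_max)
  if (isTRUE(learn)) model$synapses$weight <- res$w
  spk <- cbind(step = res$spike_step, neuron = res$spike_neuron)
  traj <- snapshot_trajectory(spk, n_steps = n_steps, fs = model$fs,
                              frame_ms = frame_ms)
  list(model = model, spikes = spk, counts = res$counts, trajectory = traj)
}

#' Snapshot trajectory of fired neurons
#'
#' Partitions an epoch into consecutive frames of `frame_ms` milliseconds
#' (the last frame may be shorter) and stores the set of neurons that
#' fired at least once within each frame.
#'
#' @param spikes matrix with columns `step`, `neuron`.
#' @param n_steps epoch length in steps.
#' @param fs sampling rate (Hz).
#' @param frame_ms frame length in ms.
#' @return A `snapshot_trajectory`: list of per-frame fired-id vectors
#'   plus frame metadata.
#' @export
snapshot_trajectory <- function(spikes, n_steps, fs, frame_ms = 50) {
  n_steps <- as.integer(n_steps)
  fs <- as.numeric(fs)
  frame_len <- max(1L, as.integer(round(frame_ms * fs / 1000)))
  n_frames <- as.integer(ceiling(n_steps / frame_len))
  frames <- rep(list(integer(0)), n_frames)
  if (nrow(spikes) > 0) {
    f <- ((spikes[, "step"] - 1L) %/% frame_len) + 1L
    for (k in unique(f)) {
      frames[[k]] <- sort(unique(spikes[f == k, "neuron"]))
    }
  }
  structure(list(frames = frames, frame_len_steps = frame_len,
                 frame_ms = frame_ms, n_steps = n_steps, fs = fs),
            class = "snapshot_trajectory")
}

#' Unsupervised STDP training over an epoch set
#'
#' Runs [run_epoch()] with learning enabled over all epochs of a
#' [encode_recording()] spike dataset, `passes` times in sequence,
#' carrying the adapted weights forward. Deterministic given the epoch
#' order (the simulation itself draws no random numbers).
#'
#' @param model a [reservoir_model()].
#' @param spike_data a `spike_dataset`, or a list of per-epoch spike tables.
#' @param passes number of passes over the epoch set.
#' @param stdp an [stdp_config()].
#' @param n_steps epoch length in steps (taken from the dataset if absent).
#' @param input_gain potential increment per input spike.
#' @return The model with trained synaptic weights.
#' @export
train_unsupervised <- function(model, spike_data, passes = 1L,
                               stdp = stdp_config(), n_steps = NULL,
                               input_gain = 1) {
  passes <- check_count(passes, "passes", min = 0L)
  epochs <- if (inherits(spike_data, "spike_dataset")) spike_data$epochs else spike_data
  n_steps <- n_steps %||% spike_data$n_steps
  if (length(epochs) < 1L && passes > 0L) stop_input("no epochs to train on")
  for (p in seq_len(passes)) {
    for (e in seq_along(epochs)) {
      model <- run_epoch(model, epochs[[e]], n_steps = n_steps, stdp = stdp,
                         learn = TRUE, input_gain = input_gain)$model
    }
  }
  model
}

#' Read-only reservoir responses for a set of epochs
#'
#' Propagates each epoch through a (typically trained) reservoir with
#' learning disabled, returning the spike record used by the deSNN
#' classifier.
#'
#' @inheritParams train_unsupervised
#' @param frame_ms snapshot frame length in ms.
#' @return List of [run_epoch()] results (without the `model` element).
#' @export
record_activity <- function(model, spike_data, n_steps = NULL,
                            frame_ms = 50, input_gain = 1) {
  epochs <- if (inherits(spike_data, "spike_dataset")) spike_data$epochs else spike_data
  n_steps <- n_steps %||% spike_data$n_steps
  lapply(epochs, function(ep) {
    r <- run_epoch(model, ep, n_steps = n_steps, learn = FALSE,
                   frame_ms = frame_ms, input_gain = input_gain)
    r[c("spikes", "counts", "trajectory")]
  })
}
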
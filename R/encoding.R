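#' Threshold-based representation (TBR) encoding parameters
#'
#' @param theta encoding threshold in signal units, or `NULL` to derive it
#'   from the signal via [tbr_theta_from_signal()] with multiplier `k`.
#' @param k threshold multiplier on the standard deviation of the first
#'   differences, used when `theta` is `NULL`.
#' @param per_channel when encoding a multichannel recording, derive one
#'   threshold per channel (`TRUE`, pooled over epochs) or a single global
#'   threshold (`FALSE`).
#' @return A `tbr_config` object.
#' @export
tbr_config <- function(theta = NULL, k = 0.5, per_channel = TRUE) {
  if (!is.null(theta) && theta <= 0) stop_input("`theta` must be positive")
  if (is.null(theta) && k <= 0) stop_input("`k` must be positive")
  structure(list(theta = theta, k = k, per_channel = isTRUE(per_channel)),
            class = "tbr_config")
}

#' Encode a signal as a bipolar spike sequence
#'
#' Delta-modulation encoder: a baseline `V` starts at the first sample and
#' tracks the signal in steps of `theta`. At each later sample `t`, a
#' positive spike is emitted and `V <- V + theta` when
#' `S(t) >= V + theta`; a negative spike is emitted and `V <- V - theta`
#' when `S(t) <= V - theta`; otherwise nothing happens. Ties emit a spike.
#'
#' @param signal numeric vector (finite values).
#' @param theta positive encoding threshold.
#' @param channel optional channel label carried in the result.
#' @return A `spike_sequence` data frame: `sample_index` (1-based, strictly
#'   increasing) and `polarity` (+1 or -1), with attributes `channel` and
#'   `n_samples`.
#' @export
tbr_encode <- function(signal, theta, channel = NA_character_) {
  if (length(signal) < 1L) stop_input("`signal` must have length >= 1")
  if (anyNA(signal) || any(!is.finite(signal))) stop_input("NaN or non-finite value in signal")
  if (theta <= 0) stop_input("`theta` must be positive")
  res <- tbr_encode_cpp(as.numeric(signal), theta)
  out <- data.frame(sample_index = res$sample_index, polarity = res$polarity)
  attr(out, "channel") <- channel
  attr(out, "n_samples") <- length(signal)
  class(out) <- c("spike_sequence", "data.frame")
  out
}

#' Derive a TBR threshold from a signal
#'
#' `theta = k * sd(diff(signal))`: proportional to the typical step size,
#' so the encoder is invariant to the overall signal scale.
#'
#' @param signal numeric vector of length >= 2.
#' @param k positive multiplier.
#' @return Positive threshold value.
#' @export
tbr_theta_from_signal <- function(signal, k = 0.5) {
  if (k <= 0) stop_input("`k` must be positive")
  if (length(signal) < 2L) stop_input("`signal` must have length >= 2")
  th <- k * sd(diff(signal))
  if (!is.finite(th) || th <= 0) {
    stop_input("signal is constant; no threshold can be derived")
  }
  th
}

#' Encode an epoched recording into spike trains
#'
#' Applies [tbr_encode()] to every channel of every epoch. Thresholds are
#' taken from `cfg$theta` when given; otherwise they are derived per
#' channel as `k * sd` of the first differences pooled across epochs
#' (`per_channel = TRUE`), or from all channels pooled
#' (`per_channel = FALSE`). Pooling across epochs keeps the threshold
#' common to all samples, so amplitude differences between classes remain
#' visible as spike-count differences.
#'
#' @param rec an [epoched_recording()].
#' @param cfg a [tbr_config()].
#' @return A `spike_dataset`: list with `epochs` (one data frame per epoch
#'   with columns `channel`, `sample_index`, `polarity`), `classes`,
#'   `channels`, `n_steps`, `fs` and the per-channel `theta` used.
#' @export
encode_recording <- function(rec, cfg = tbr_config()) {
  stopifnot(inherits(rec, "epoched_recording"))
  nch <- length(rec$channels)
  if (!is.null(cfg$theta)) {
    theta <- rep(cfg$theta, nch)
  } else {
    ns <- dim(rec$data)[2]
    diffs <- rec$data[, -1, , drop = FALSE] - rec$data[, -ns, , drop = FALSE]
    if (cfg$per_channel) {
      theta <- vapply(seq_len(nch), function(i) cfg$k * sd(diffs[i, , ]), 0)
    } else {
      theta <- rep(cfg$k * sd(diffs), nch)
    }
    if (any(!is.finite(theta) | theta <= 0)) {
      stop_input("constant channel; cannot derive TBR threshold")
    }
  }
  names(theta) <- rec$channels
  epochs <- lapply(seq_len(dim(rec$data)[3]), function(e) {
    per_ch <- lapply(seq_len(nch), function(i) {
      s <- tbr_encode(rec$data[i, , e], theta[i], channel = rec$channels[i])
      if (nrow(s) == 0) return(NULL)
      data.frame(channel = rec$channels[i], sample_index = s$sample_index,
                 polarity = s$polarity, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_ch)
    if (is.null(out)) out <- data.frame(channel = character(0),
                                        sample_index = integer(0),
                                        polarity = integer(0))
    out
  })
  structure(list(epochs = epochs, classes = rec$classes,
                 channels = rec$channels, n_steps = dim(rec$data)[2],
                 fs = rec$fs, theta = theta),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> %d epochs x %d channels x %d steps @ %g Hz\n",
              length(x$epochs), length(x$channels), x$n_steps, x$fs))
  invisible(x)
}

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts one half-open window `[onset + window_ms[1], onset + window_ms[2])`
#' per event out of a continuous channels x samples matrix. Sample
#' indexing is 0-based in time: an event at 0 ms with window `[0, 200)` at
#' 256 Hz covers samples 0..50 (matrix columns 1..51). Overlapping events
#' are allowed; every epoch is returned unchanged.
#'
#' @param continuous numeric matrix, channels x samples.
#' @param events data frame with `onset_ms` and optionally `class`.
#' @param window_ms half-open peristimulus window (ms).
#' @param fs sampling rate (Hz).
#' @param channels channel labels; default rownames of `continuous`.
#' @return An [epoched_recording()].
#' @export
extract_epochs <- function(continuous, events, window_ms = c(0, 200), fs = 256,
                           channels = rownames(continuous)) {
  if (!is.matrix(continuous)) stop_input("`continuous` must be a matrix")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(continuous)))
  n_samp <- window_n_samples(window_ms, fs)
  n_total <- ncol(continuous)
  classes <- if ("class" %in% names(events)) as.character(events$class)
             else rep(NA_character_, nrow(events))
  data <- array(0, dim = c(nrow(continuous), n_samp, nrow(events)))
  for (e in seq_len(nrow(events))) {
    start <- round((events$onset_ms[e] + window_ms[1]) * fs / 1000)
    if (start < 0 || start + n_samp > n_total) {
      stop_input("event %d window [%d, %d) outside recording of %d samples",
                 e, start, start + n_samp, n_total)
    }
    data[, , e] <- continuous[, (start + 1):(start + n_samp), drop = FALSE]
  }
  epoched_recording(data, fs = fs, channels = channels, classes = classes,
                    window_ms = window_ms)
}
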
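# All writers print doubles with 17 significant digits so that
# write -> read round-trips are bit identical.
fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("#%s\t%s", k, paste(meta[[k]], collapse = ",")), con)
  }
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t")[[1]]
    meta[[kv[1]]] <- strsplit(kv[2] %||% "", ",")[[1]]
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  if (length(body) == 0) stop_format("no header row in %s", path)
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

# Delimited reader with a required-column check (whitespace- or
# tab-separated, header row mandatory).
read_delim_file <- function(path, need_cols) {
  if (!nzchar(path) || !file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(need_cols, names(df))
  if (length(missing) > 0) {
    stop_format("malformed header in %s: missing column(s) %s", path,
                paste(missing, collapse = ", "))
  }
  df
}

#' Write / read an epoched recording
#'
#' Plain-text container: `#` metadata lines (`fs`, `window_ms`, `classes`)
#' followed by a tab-separated table with one row per epoch x channel and
#' one column per sample. Round-trips are bit identical.
#'
#' @param rec an [epoched_recording()].
#' @param path output file.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the reconstructed [epoched_recording()].
#' @export
write_epochs <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- dim(rec$data)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(e) {
    m <- rec$data[, , e, drop = FALSE]
    dim(m) <- d[1:2]
    data.frame(epoch = e, channel = rec$channels, m, check.names = FALSE)
  }))
  names(rows) <- c("epoch", "channel", paste0("s", seq_len(d[2])))
  write_tsv(rows, path, meta = list(fs = fmt_num(rec$fs),
                                    window_ms = fmt_num(rec$window_ms),
                                    classes = rec$classes))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- read_tsv(path)
  meta <- attr(df, "meta")
  need <- c("epoch", "channel")
  if (!all(need %in% names(df))) stop_format("malformed epoch file %s", path)
  channels <- unique(df$channel)
  epochs <- sort(unique(df$epoch))
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  data <- array(0, dim = c(length(channels), length(scols), length(epochs)))
  for (e in seq_along(epochs)) {
    sub <- df[df$epoch == epochs[e], , drop = FALSE]
    data[, , e] <- as.matrix(sub[match(channels, sub$channel), scols])
  }
  epoched_recording(data, fs = as.numeric(meta$fs), channels = channels,
                    classes = meta$classes,
                    window_ms = as.numeric(meta$window_ms))
}

#' Write / read an event table
#'
#' @param events data frame with `onset_ms`, `stimulus_id`, `class` (and
#'   optionally `block`).
#' @param path file path.
#' @return The path (writer, invisibly) or the event data frame (reader).
#' @export
write_events <- function(events, path) {
  write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  if (!all(c("onset_ms", "class") %in% names(df))) {
    stop_format("malformed event file %s", path)
  }
  attr(df, "meta") <- NULL
  df
}

#' Write / read an encoded spike dataset
#'
#' Delimited event table (`epoch`, `channel`, `sample_index`, `polarity`)
#' with metadata lines carrying the epoch count, step count, sampling rate,
#' channel list, class labels and per-channel thresholds. Round-trips
#' preserve every event exactly.
#'
#' @param sd a `spike_dataset` from [encode_recording()].
#' @param path file path.
#' @return The path (writer, invisibly) or a `spike_dataset` (reader).
#' @export
write_spikes <- function(sd, path) {
  stopifnot(inherits(sd, "spike_dataset"))
  rows <- do.call(rbind, lapply(seq_along(sd$epochs), function(e) {
    ep <- sd$epochs[[e]]
    if (nrow(ep) == 0) return(NULL)
    cbind(epoch = e, ep)
  }))
  if (is.null(rows)) rows <- data.frame(epoch = integer(0), channel = character(0),
                                        sample_index = integer(0), polarity = integer(0))
  write_tsv(rows, path,
            meta = list(n_epochs = length(sd$epochs), n_steps = sd$n_steps,
                        fs = fmt_num(sd$fs), channels = sd$channels,
                        classes = sd$classes, theta = fmt_num(sd$theta)))
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- read_tsv(path)
  meta <- attr(df, "meta")
  need <- c("epoch", "channel", "sample_index", "polarity")
  if (!all(need %in% names(df))) stop_format("malformed spike file %s", path)
  n_epochs <- as.integer(meta$n_epochs)
  epochs <- lapply(seq_len(n_epochs), function(e) {
    sub <- df[df$epoch == e, c("channel", "sample_index", "polarity")]
    rownames(sub) <- NULL
    sub
  })
  structure(list(epochs = epochs, classes = meta$classes,
                 channels = meta$channels, n_steps = as.integer(meta$n_steps),
                 fs = as.numeric(meta$fs),
                 theta = setNames(as.numeric(meta$theta), meta$channels)),
            class = "spike_dataset")
}

#' Write / read a synapse set
#'
#' @param syn a `synapse_set` (`pre`, `post`, `weight`).
#' @param path file path.
#' @return The path (writer, invisibly) or a `synapse_set` (reader).
#' @export
write_synapses <- function(syn, path) {
  write_tsv(as.data.frame(syn), path,
            meta = list(n_neurons = attr(syn, "n_neurons") %||% max(syn$pre, syn$post, 0)))
  invisible(path)
}

#' @rdname write_synapses
#' @export
read_synapses <- function(path) {
  df <- read_tsv(path)
  if (!all(c("pre", "post", "weight") %in% names(df))) {
    stop_format("malformed synapse file %s", path)
  }
  meta <- attr(df, "meta")
  out <- df[, c("pre", "post", "weight")]
  attr(out, "n_neurons") <- as.integer(meta$n_neurons)
  class(out) <- c("synapse_set", "data.frame")
  out
}

#' Write / read a neuron atlas
#'
#' @param atlas a `neuron_atlas` from [build_atlas()].
#' @param path file path.
#' @return The path (writer, invisibly) or a `neuron_atlas` (reader).
#' @export
write_atlas <- function(atlas, path) {
  write_tsv(as.data.frame(atlas), path,
            meta = list(resolution = fmt_num(attr(atlas, "resolution"))))
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- read_tsv(path)
  need <- c("id", "x", "y", "z", "gx", "gy", "gz", "region", "is_input", "channel")
  if (!all(need %in% names(df))) stop_format("malformed atlas file %s", path)
  meta <- attr(df, "meta")
  df$channel[df$channel == "NA"] <- NA_character_
  for (col in c("x", "y", "z")) df[[col]] <- as.numeric(df[[col]])
  attr(df, "meta") <- NULL
  attr(df, "resolution") <- as.numeric(meta$resolution)
  class(df) <- c("neuron_atlas", "data.frame")
  df
}

#' Write / read a snapshot trajectory
#'
#' Per-frame fired-neuron lists as a long `frame`, `neuron` table;
#' metadata keeps the frame geometry so empty frames survive round-trips.
#'
#' @param traj a `snapshot_trajectory`.
#' @param path file path.
#' @return The path (writer, invisibly) or a `snapshot_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "snapshot_trajectory"))
  rows <- do.call(rbind, lapply(seq_along(traj$frames), function(f) {
    ids <- traj$frames[[f]]
    if (length(ids) == 0) return(NULL)
    data.frame(frame = f, neuron = ids)
  }))
  if (is.null(rows)) rows <- data.frame(frame = integer(0), neuron = integer(0))
  write_tsv(rows, path,
            meta = list(n_frames = length(traj$frames),
                        frame_len_steps = traj$frame_len_steps,
                        frame_ms = fmt_num(traj$frame_ms),
                        n_steps = traj$n_steps, fs = fmt_num(traj$fs)))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_tsv(path)
  meta <- attr(df, "meta")
  n_frames <- as.integer(meta$n_frames)
  frames <- lapply(seq_len(n_frames), function(f) {
    sort(df$neuron[df$frame == f])
  })
  structure(list(frames = frames,
                 frame_len_steps = as.integer(meta$frame_len_steps),
                 frame_ms = as.numeric(meta$frame_ms),
                 n_steps = as.integer(meta$n_steps), fs = as.numeric(meta$fs)),
            class = "snapshot_trajectory")
}

#' Read a continuous multichannel recording
#'
#' Tab- or whitespace-separated matrix file: header row, first column
#' `channel` holding the labels, remaining columns one sample each.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (files carry no rate; it must be given).
#' @return A `continuous_recording`: list with `data` (channels x samples
#'   matrix), `channels`, `fs`.
#' @export
read_recording <- function(path, fs) {
  df <- read_delim_file(path, "channel")
  m <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric samples in %s", path)
  rownames(m) <- df$channel
  structure(list(data = m, channels = df$channel, fs = fs),
            class = "continuous_recording")
}

#' Default run configuration
#'
#' Flat, sectioned key-value configuration covering every stage. Each
#' field has a documented default (see the constructor of the matching
#' section: [paradigm_spec()], [erp_template_spec()], [tbr_config()],
#' [small_world_config()], [lif_config()], [stdp_config()],
#' [desnn_config()], [param_grid()], [pipeline_config()]).
#'
#' @return Nested list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    data = list(n_participants = 20L, mode = "block_average", fs = 256,
                window_ms = c(0, 200)),
    paradigm = list(n_blocks = 3L, target_reps = 28L, n_nontarget_logos = 8L,
                    nontarget_reps = 14L, stim_duration_ms = 200,
                    isi_range_ms = c(1300, 1500), familiar_fraction = 0.5),
    template = list(noise_sd = 2, pink_sd = 2, pink_exponent = 1),
    tbr = list(theta = NULL, k = 0.5, per_channel = TRUE),
    small_world = list(radius = 2L, p0 = 0.9, decay = 2.2, pos_fraction = 0.8,
                       w_init_max = 0.1),
    lif = list(theta_fire = 0.5, tau_leak_ms = 10, refractory_steps = 1L),
    stdp = list(rate = 0.01, a_plus = 1, a_minus = 1, tau_plus_ms = 10,
                tau_minus_ms = 10, w_min = -1, w_max = 1),
    desnn = list(mod = 0.4, drift = 0.005, drift_decay = FALSE,
                 mode = "weight_similarity"),
    grid = list(rate = c(0.001, 0.1), threshold = c(0.1, 1),
                mod = c(0.1, 0.9), n_steps = 10L),
    pipeline = list(resolution = 12, passes = 1L, frame_ms = 50,
                    input_gain = 1, negative_input = "signed", init_seed = 42L)
  )
}

#' Read a run configuration file
#'
#' YAML file with the sections of [default_run_config()]; unspecified
#' fields keep their defaults and unknown sections or keys are rejected.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user %||% list(), "")
}

merge_config <- function(defaults, user, prefix) {
  if (!is.list(user)) stop_format("config section '%s' must be a mapping", prefix)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_format("unknown config key(s): %s",
                paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build stage objects from a run configuration
#'
#' @param rc configuration list from [read_run_config()] or
#'   [default_run_config()].
#' @return List with `paradigm`, `template`, `grid` and `pipeline`
#'   (a [pipeline_config()]) objects.
#' @export
run_config_objects <- function(rc) {
  template <- erp_template_spec(noise_sd = rc$template$noise_sd,
                                pink_sd = rc$template$pink_sd,
                                pink_exponent = rc$template$pink_exponent)
  paradigm <- do.call(paradigm_spec, rc$paradigm)
  grid <- do.call(param_grid, rc$grid)
  pipeline <- pipeline_config(
    resolution = rc$pipeline$resolution,
    tbr = do.call(tbr_config, rc$tbr),
    small_world = do.call(small_world_config, rc$small_world),
    lif = do.call(lif_config, rc$lif),
    stdp = do.call(stdp_config, rc$stdp),
    desnn = do.call(desnn_config, rc$desnn),
    passes = rc$pipeline$passes, frame_ms = rc$pipeline$frame_ms,
    input_gain = rc$pipeline$input_gain,
    negative_input = rc$pipeline$negative_input,
    init_seed = rc$pipeline$init_seed)
  list(paradigm = paradigm, template = template, grid = grid,
       pipeline = pipeline)
}

#' Write a run manifest
#'
#' Records the full configuration, the global seed and the package
#' version alongside every run's outputs.
#'
#' @param rc configuration list.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(rc, path) {
  rc$package_version <- as.character(packageVersion("snnerp"))
  yaml::write_yaml(rc, path)
  invisible(path)
}
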
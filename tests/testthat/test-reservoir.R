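# Hand-built two-neuron atlas: neuron 1 is the input for channel "A",
# neuron 2 its target.
toy_atlas <- function(n = 2, input_channels = "A") {
  atlas <- data.frame(id = seq_len(n), x = (seq_len(n) - 1) * 10, y = 0, z = 0,
                      gx = seq_len(n) - 1, gy = 0, gz = 0,
                      region = "Occipital", is_input = FALSE,
                      channel = NA_character_)
  atlas$is_input[seq_along(input_channels)] <- TRUE
  atlas$channel[seq_along(input_channels)] <- input_channels
  attr(atlas, "resolution") <- 10
  class(atlas) <- c("neuron_atlas", "data.frame")
  atlas
}

toy_synapses <- function(pre, post, weight, n_neurons) {
  syn <- data.frame(pre = pre, post = post, weight = weight)
  attr(syn, "n_neurons") <- n_neurons
  class(syn) <- c("synapse_set", "data.frame")
  syn
}

test_that("the STDP window follows the signed-exponential rule", {
  cfg <- stdp_config(rate = 1, a_plus = 1, a_minus = 1,
                     tau_plus_ms = 10, tau_minus_ms = 10)
  expect_equal(stdp_delta(0, cfg), -1)           # boundary branch, exp(0) = 1
  expect_equal(stdp_delta(-10, cfg), exp(-1))    # dt = -tau_plus
  expect_equal(stdp_delta(10, cfg), -exp(-1))
  dts <- seq(-50, 50, by = 2.5)
  d <- stdp_delta(dts, cfg)
  expect_true(all(d[dts < 0] > 0) && all(d[dts >= 0] < 0))
  # |change| decreases monotonically with |dt| on each branch
  expect_true(all(diff(abs(d[dts < 0])) > 0))
  expect_true(all(diff(abs(d[dts >= 0])) < 0))
  expect_true(all(abs(stdp_delta(c(-500, 500), cfg)) < 1e-20))
  # rate scales the whole window
  expect_equal(stdp_delta(dts, stdp_config(rate = 0.01)),
               0.01 * stdp_delta(dts, cfg))
  expect_error(stdp_delta(Inf, cfg), class = "snnerp_input_error")
})

test_that("a single spike relays across a supra-threshold synapse", {
  model <- reservoir_model(toy_atlas(), toy_synapses(1, 2, 0.6, 2),
                           lif_config(theta_fire = 0.5), fs = 1000)
  spikes <- data.frame(channel = "A", sample_index = 1L, polarity = 1L)
  r <- run_epoch(model, spikes, n_steps = 5, learn = FALSE)
  expect_equal(r$spikes, cbind(step = c(1L, 2L), neuron = c(1L, 2L)))
  expect_equal(r$counts, c(1L, 1L))
  # sub-threshold weight: no relay
  weak <- reservoir_model(toy_atlas(), toy_synapses(1, 2, 0.4, 2),
                          lif_config(theta_fire = 0.5, tau_leak_ms = 1e-6), fs = 1000)
  expect_equal(run_epoch(weak, spikes, 5, learn = FALSE)$counts, c(1L, 0L))
})

test_that("zero input leaves the reservoir silent and the weights untouched", {
  atlas <- build_atlas(20)
  syn <- init_small_world(atlas, small_world_config(seed = 4))
  model <- reservoir_model(atlas, syn, lif_config(), fs = 256)
  empty <- data.frame(channel = character(0), sample_index = integer(0),
                      polarity = integer(0))
  r <- run_epoch(model, empty, n_steps = 30, learn = TRUE)
  expect_equal(nrow(r$spikes), 0L)
  expect_identical(r$model$synapses$weight, syn$weight)
})

test_that("negative input spikes are signed by default, rerouted in separate-line mode", {
  spikes_neg <- data.frame(channel = "A", sample_index = 1L, polarity = -1L)
  m <- reservoir_model(toy_atlas(3), toy_synapses(1, 2, 0.6, 3), lif_config(), fs = 1000)
  expect_equal(nrow(run_epoch(m, spikes_neg, 5, learn = FALSE)$spikes), 0L)
  ms <- reservoir_model(toy_atlas(3), toy_synapses(1, 2, 0.6, 3), lif_config(),
                        fs = 1000, negative_input = "separate_line")
  r <- run_epoch(ms, spikes_neg, 5, learn = FALSE)
  expect_equal(unname(ms$neg_input_map[["A"]]), 2L) # next-nearest neuron
  expect_true(2L %in% r$spikes[, "neuron"])
})

test_that("refractory neurons skip a step", {
  model <- reservoir_model(toy_atlas(1), toy_synapses(integer(0), integer(0),
                                                      numeric(0), 1),
                           lif_config(theta_fire = 0.5, refractory_steps = 1L),
                           fs = 1000)
  dense <- data.frame(channel = "A", sample_index = 1:10, polarity = 1L)
  r <- run_epoch(model, dense, 10, learn = FALSE)
  expect_equal(r$spikes[, "step"], seq(1L, 9L, by = 2L))
})

test_that("repeated pre-before-post pairing strengthens the synapse to its bound", {
  atlas <- toy_atlas(2, input_channels = c("A", "B"))
  stdp <- stdp_config(rate = 0.05, w_max = 0.9)
  spikes <- data.frame(channel = rep(c("A", "B"), 10),
                       sample_index = rep(seq(1, 40, by = 4), each = 2) + c(0L, 1L),
                       polarity = 1L)
  model <- reservoir_model(atlas, toy_synapses(1, 2, 0.1, 2), lif_config(), fs = 1000)
  w_hist <- numeric(6)
  for (k in 1:6) {
    model <- run_epoch(model, spikes, 41, stdp = stdp, learn = TRUE)$model
    w_hist[k] <- model$synapses$weight
  }
  expect_true(all(diff(w_hist) >= 0))
  expect_gt(w_hist[1], 0.1)
  expect_lte(max(w_hist), 0.9)
})

test_that("weights stay inside the configured bounds during learning", {
  atlas <- build_atlas(20)
  syn <- init_small_world(atlas, small_world_config(seed = 5))
  model <- reservoir_model(atlas, syn, lif_config(theta_fire = 0.2), fs = 256)
  set.seed(2)
  ep <- data.frame(channel = sample(montage_channels(), 120, replace = TRUE),
                   sample_index = sort(sample.int(51, 120, replace = TRUE)),
                   polarity = sample(c(1L, -1L), 120, replace = TRUE))
  stdp <- stdp_config(rate = 0.2, w_min = -0.15, w_max = 0.15)
  model <- train_unsupervised(model, rep(list(ep), 4), n_steps = 51, stdp = stdp)
  expect_true(all(model$synapses$weight >= -0.15 - 1e-12))
  expect_true(all(model$synapses$weight <= 0.15 + 1e-12))
})

test_that("neurons without a short enough input path cannot fire early", {
  skip_if_not_installed("igraph")
  inst <- random_instance(31, n_neurons = 15, n_steps = 25)
  res <- snnerp:::lif_stdp_run_cpp(
    inst$n_neurons, inst$edges$pre - 1L, inst$edges$post - 1L,
    abs(inst$edges$weight) * 2, # strong positive weights to maximise firing
    inst$events$step, inst$events$neuron - 1L, abs(inst$events$amp),
    inst$n_steps, 0.3, 0.9, 1L, FALSE, 0, 1, 1, 2.56, 2.56, -1, 1)
  g <- igraph::graph_from_data_frame(inst$edges[, c("pre", "post")],
                                     vertices = data.frame(name = 1:15))
  dist_in <- suppressWarnings(
    apply(igraph::distances(g, v = as.character(1:3), mode = "out"), 2, min))
  first_ev <- min(inst$events$step)
  for (i in seq_len(inst$n_neurons)) {
    ft <- res$spike_step[res$spike_neuron == i]
    if (length(ft) > 0) {
      expect_gte(min(ft), first_ev + dist_in[[as.character(i)]])
    }
  }
})

test_that("compiled simulator matches the plain-R reference step for step", {
  for (seed in 1:6) {
    for (learn in c(FALSE, TRUE)) {
      inst <- random_instance(seed)
      ref <- lif_stdp_reference(inst$n_neurons, inst$edges, inst$events,
                                inst$n_steps, theta_fire = 0.4, decay = 0.85,
                                refractory = 1L, learn = learn, rate = 0.05,
                                a_plus = 1, a_minus = 0.8, tau_plus = 2.5,
                                tau_minus = 3, w_min = -1, w_max = 1)
      got <- snnerp:::lif_stdp_run_cpp(
        inst$n_neurons, inst$edges$pre - 1L, inst$edges$post - 1L,
        inst$edges$weight, inst$events$step, inst$events$neuron - 1L,
        inst$events$amp, inst$n_steps, 0.4, 0.85, 1L, learn, 0.05,
        1, 0.8, 2.5, 3, -1, 1)
      expect_equal(got$w, ref$w, tolerance = 1e-12)
      expect_equal(cbind(step = got$spike_step, neuron = got$spike_neuron),
                   ref$spikes, ignore_attr = TRUE)
      expect_equal(got$counts, ref$counts, ignore_attr = TRUE)
    }
  }
})

test_that("unsupervised training is deterministic and no-op at zero passes", {
  atlas <- build_atlas(25)
  syn <- init_small_world(atlas, small_world_config(seed = 6))
  model <- reservoir_model(atlas, syn, lif_config(theta_fire = 0.2), fs = 256)
  set.seed(3)
  eps <- lapply(1:3, function(k) {
    data.frame(channel = sample(montage_channels(), 60, replace = TRUE),
               sample_index = sort(sample.int(51, 60, replace = TRUE)),
               polarity = sample(c(1L, -1L), 60, replace = TRUE))
  })
  expect_identical(train_unsupervised(model, eps, passes = 0, n_steps = 51),
                   model)
  m1 <- train_unsupervised(model, eps, passes = 2, n_steps = 51)
  m2 <- train_unsupervised(model, eps, passes = 2, n_steps = 51)
  expect_identical(m1$synapses$weight, m2$synapses$weight)
  expect_false(identical(m1$synapses$weight, model$synapses$weight))
})

test_that("sustained drive strengthens the driven pathway above the reservoir mean", {
  atlas <- build_atlas(20)
  drive <- data.frame(channel = "O1", sample_index = seq(1, 51, by = 2),
                      polarity = 1L)
  stdp <- stdp_config(rate = 0.02, a_minus = 0)
  for (s in 1:3) {
    syn0 <- init_small_world(atlas, small_world_config(seed = s))
    model <- reservoir_model(atlas, syn0,
                             lif_config(theta_fire = 0.35, tau_leak_ms = 30),
                             fs = 256)
    model <- train_unsupervised(model, rep(list(drive), 3), n_steps = 51,
                                stdp = stdp)
    id <- model$input_map[["O1"]]
    driven <- mean(model$synapses$weight[model$synapses$pre == id])
    expect_gt(driven, mean(model$synapses$weight))
  }
})

test_that("snapshot frames tile the epoch", {
  spikes <- cbind(step = c(1L, 13L, 14L, 40L), neuron = c(5L, 6L, 5L, 9L))
  traj <- snapshot_trajectory(spikes, n_steps = 40, fs = 256, frame_ms = 50)
  expect_equal(traj$frame_len_steps, 13L) # round(0.05 * 256)
  expect_length(traj$frames, 4L)          # ceiling(40 / 13)
  expect_equal(traj$frames[[1]], c(5L, 6L))
  expect_equal(traj$frames[[2]], 5L)
  expect_equal(traj$frames[[3]], integer(0))
  expect_equal(traj$frames[[4]], 9L)
})

test_that("input spikes beyond the epoch are rejected", {
  model <- reservoir_model(toy_atlas(), toy_synapses(1, 2, 0.6, 2),
                           lif_config(), fs = 1000)
  bad <- data.frame(channel = "A", sample_index = 10L, polarity = 1L)
  expect_error(run_epoch(model, bad, n_steps = 5), class = "snnerp_input_error")
  unknown <- data.frame(channel = "Z", sample_index = 1L, polarity = 1L)
  expect_error(run_epoch(model, unknown, n_steps = 5), class = "snnerp_input_error")
})
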
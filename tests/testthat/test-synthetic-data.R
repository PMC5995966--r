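test_that("default oddball schedule has the prescribed block composition", {
  sched <- generate_schedule(paradigm_spec(), seed = 7)
  expect_equal(stimuli_per_block(paradigm_spec()), 140L)
  for (b in 1:3) {
    blk <- sched[sched$block == b, ]
    expect_equal(nrow(blk), 140L)
    expect_equal(sum(blk$class == "target"), 28L)
    tab <- table(blk$stimulus_id[blk$class != "target"])
    expect_equal(length(tab), 8L)
    expect_true(all(tab == 14L))
    expect_equal(sum(blk$class == "familiar"), 4L * 14L)
    expect_equal(sum(blk$class == "unfamiliar"), 4L * 14L)
  }
})

test_that("schedule onsets respect stimulus duration plus the ISI range", {
  spec <- paradigm_spec()
  sched <- generate_schedule(spec, seed = 3)
  for (b in unique(sched$block)) {
    gaps <- diff(sched$onset_ms[sched$block == b])
    expect_true(all(gaps >= spec$stim_duration_ms + spec$isi_range_ms[1]))
    expect_true(all(gaps <= spec$stim_duration_ms + spec$isi_range_ms[2]))
    expect_equal(sched$onset_ms[sched$block == b][1], 0)
  }
})

test_that("schedule generation is deterministic given the seed and validates", {
  expect_identical(generate_schedule(seed = 11), generate_schedule(seed = 11))
  expect_false(identical(generate_schedule(seed = 11), generate_schedule(seed = 12)))
  one <- generate_schedule(paradigm_spec(target_reps = 1, n_nontarget_logos = 0),
                           seed = 1)
  expect_equal(nrow(one), 3L) # one event per block
  expect_error(paradigm_spec(n_blocks = 0), class = "snnerp_input_error")
  expect_error(paradigm_spec(target_reps = -1), class = "snnerp_input_error")
  expect_error(paradigm_spec(isi_range_ms = c(1500, 1300)),
               class = "snnerp_input_error")
  expect_error(paradigm_spec(target_reps = 0, n_nontarget_logos = 0),
               class = "snnerp_input_error")
})

test_that("epoch generation has the documented shape and reproducibility", {
  sched <- generate_schedule(seed = 5)[1:10, ]
  tpl <- erp_template_spec()
  rec <- generate_epochs(tpl, sched, fs = 256, window_ms = c(0, 200), seed = 2)
  expect_s3_class(rec, "epoched_recording")
  expect_equal(dim(rec$data), c(19L, 51L, 10L)) # round(0.2 * 256) = 51
  expect_equal(rec$classes, as.character(sched$class))
  rec2 <- generate_epochs(tpl, sched, fs = 256, window_ms = c(0, 200), seed = 2)
  expect_identical(rec$data, rec2$data)
  expect_error(generate_epochs(tpl, sched, window_ms = c(0, 100)),
               class = "snnerp_input_error") # P200 outside the window
})

test_that("noiseless epochs equal the deterministic class template", {
  comp <- data.frame(component = "P100", class = c("familiar", "unfamiliar"),
                     channel = "O1", latency_ms = 100, width_ms = 15,
                     amplitude_uv = c(5, 2))
  tpl <- erp_template_spec(comp, noise_sd = 0, pink_sd = 0)
  sched <- data.frame(class = c("familiar", "unfamiliar"))
  rec <- generate_epochs(tpl, sched, channels = c("O1", "O2"), fs = 256,
                         window_ms = c(0, 200), seed = 1)
  t_ms <- (0:50) * 1000 / 256
  expect_equal(rec$data["O1", , 1], 5 * exp(-(t_ms - 100)^2 / (2 * 15^2)))
  # classes differ only on the channel with differing amplitudes
  expect_equal(rec$data["O2", , 1], rec$data["O2", , 2])
  expect_false(isTRUE(all.equal(rec$data["O1", , 1], rec$data["O1", , 2])))
  # the component peak sits at the specified latency sample
  expect_equal(which.max(rec$data["O1", , 1]), round(100 * 256 / 1000) + 1L)
})

test_that("unknown channel in the amplitude map is rejected", {
  comp <- data.frame(component = "P100", class = "familiar", channel = "XX",
                     latency_ms = 100, width_ms = 15, amplitude_uv = 5)
  tpl <- erp_template_spec(comp, noise_sd = 0, pink_sd = 0)
  expect_error(generate_epochs(tpl, data.frame(class = "familiar"),
                               channels = c("O1", "O2")),
               class = "snnerp_input_error")
})

test_that("epoch averaging is the arithmetic mean and converges to the template", {
  comp <- data.frame(component = "N100", class = "familiar", channel = "O1",
                     latency_ms = 120, width_ms = 20, amplitude_uv = -4)
  sched <- data.frame(class = rep("familiar", 500))
  tpl <- erp_template_spec(comp, noise_sd = 1, pink_sd = 0)
  rec <- generate_epochs(tpl, sched, channels = "O1", seed = 9)
  # single epoch averages to itself
  one <- epoched_recording(rec$data[, , 1, drop = FALSE], rec$fs, "O1", "familiar")
  expect_equal(average_epochs(one, "familiar")[1, ], rec$data[1, , 1])
  expect_error(average_epochs(one, "unfamiliar"), class = "snnerp_input_error")
  # n = 500 Monte-Carlo mean is within a few standard errors of the template
  t_ms <- (0:50) * 1000 / 256
  template <- -4 * exp(-(t_ms - 120)^2 / (2 * 20^2))
  avg <- average_epochs(rec, "familiar")[1, ]
  expect_true(max(abs(avg - template)) < 5 / sqrt(500))
  expect_lt(abs(mean(avg - template)), 3 / sqrt(500 * 51))
})

test_that("simulated datasets follow the participant x block x class layout", {
  tpl <- erp_template_spec(noise_sd = 0.5, pink_sd = 0.5)
  ds <- simulate_dataset(n_participants = 2, template = tpl, seed = 4)
  expect_equal(dim(ds$data), c(19L, 51L, 12L)) # 2 x 3 blocks x 2 classes
  meta <- attr(ds, "meta")
  expect_equal(table(meta$class), table(rep(c("familiar", "unfamiliar"), 6)))
  expect_equal(unique(meta$participant), 1:2)
  expect_identical(ds$data,
                   simulate_dataset(n_participants = 2, template = tpl, seed = 4)$data)
  st <- simulate_dataset(n_participants = 1, template = tpl,
                         mode = "single_trial", seed = 4)
  expect_equal(dim(st$data)[3], 6L)
})
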
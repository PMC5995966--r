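test_that("confusion metrics match hand arithmetic and the brute-force tally", {
  cm <- matrix(c(52, 10, 8, 50), 2, 2) # rows = real, cols = predicted
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 100 * 52 / 60)
  expect_equal(m$specificity, 100 * 50 / 60)
  prec <- 52 / 62; rec <- 52 / 60
  expect_equal(m$f_score, 100 * 2 * prec * rec / (prec + rec))
  # same numbers from a per-sample tally on the expanded label vectors
  real <- rep(c("pos", "neg"), c(60, 60))
  pred <- c(rep(c("pos", "neg"), c(52, 8)), rep(c("pos", "neg"), c(10, 50)))
  ref <- metrics_reference(real, pred, "pos")
  expect_equal(m$accuracy, ref$accuracy)
  expect_equal(m$sensitivity, ref$sensitivity)
  expect_equal(m$specificity, ref$specificity)
  expect_equal(m$f_score, ref$f_score)
})

test_that("metrics agree with brute force on random confusion tables", {
  set.seed(21)
  for (k in 1:20) {
    cm <- matrix(rpois(4, 15), 2, 2)
    real <- rep(c("a", "b"), times = rowSums(cm))
    pred <- c(rep(c("a", "b"), cm[1, ]), rep(c("a", "b"), cm[2, ]))
    m <- confusion_metrics(cm)
    ref <- metrics_reference(real, pred, "a")
    expect_equal(m$accuracy, ref$accuracy)
    expect_equal(m$sensitivity, ref$sensitivity)
    expect_equal(m$specificity, ref$specificity)
  }
})

test_that("degenerate confusion tables give NA, perfect ones give 100", {
  p <- confusion_metrics(matrix(c(30, 0, 0, 30), 2, 2))
  expect_true(all(unlist(p[c("accuracy", "f_score", "sensitivity",
                             "specificity")]) == 100))
  z <- confusion_metrics(matrix(c(0, 5, 0, 5), 2, 2))
  expect_true(is.na(z$sensitivity)) # no positive samples: undefined, not 0
  expect_true(is.na(z$f_score))
  expect_equal(z$specificity, 50)
  expect_error(confusion_metrics(matrix(-1, 2, 2)), class = "snnerp_input_error")
  expect_error(confusion_metrics(matrix(1, 3, 3)), class = "snnerp_input_error")
})

test_that("coin-flip predictions on balanced labels score near 50%", {
  set.seed(33)
  real <- rep(c("a", "b"), 1000)
  pred <- sample(c("a", "b"), 2000, replace = TRUE)
  cm <- table(factor(real, c("a", "b")), factor(pred, c("a", "b")))
  expect_equal(confusion_metrics(cm)$accuracy, 50, tolerance = 0.1) # +-5pp
})

test_that("parameter grids span the ranges inclusively", {
  g <- param_grid()
  expect_equal(nrow(g), 1000L)
  expect_equal(length(unique(g$rate)), 10L)
  expect_equal(range(g$rate), c(0.001, 0.1))
  expect_equal(range(g$threshold), c(0.1, 1))
  expect_equal(range(g$mod), c(0.1, 0.9))
  one <- param_grid(rate = c(0.01, 0.01), threshold = c(0.5, 0.5),
                    mod = c(0.4, 0.4), n_steps = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(as.numeric(one), c(0.01, 0.5, 0.4))
  mixed <- param_grid(n_steps = c(2, 3, 4))
  expect_equal(nrow(mixed), 24L)
  expect_error(param_grid(n_steps = 0), class = "snnerp_input_error")
})

test_that("vote-based selection prefers dominating combinations", {
  combos <- data.frame(rate = c(0.1, 0.2, 0.3), threshold = 0.5, mod = 0.4)
  dominating <- rbind(c(1, 1, 1, 1), c(0, 1, 0, 1), c(1, 1, 1, 0))
  sel <- snnerp:::select_best_combo(dominating, combos)
  expect_equal(sel$index, 1L)
  expect_equal(sel$votes, c(4, 2, 3))
  # vote tie resolved by mean accuracy, then lexicographic order
  tied <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 1))
  expect_equal(snnerp:::select_best_combo(tied, combos[1:2, ])$index, 2L)
  lex <- rbind(c(1, 0), c(1, 0))
  expect_equal(snnerp:::select_best_combo(lex, combos[c(3, 1), ])$index, 2L)
})

test_that("leave-one-out cross-validation builds one fold per sample", {
  tpl <- high_snr_template()
  ds <- simulate_dataset(n_participants = 1, template = tpl, seed = 2)
  cfg <- synthetic_study_config(resolution = 25)
  cv <- loocv(ds, cfg)
  expect_s3_class(cv, "cv_report")
  expect_equal(cv$n, 6L)
  expect_equal(nrow(cv$predictions), 6L)
  expect_true(all(cv$predictions$train_n == 5L))
  expect_equal(sum(cv$confusion), 6L)
  expect_true(cv$accuracy >= 0 && cv$accuracy <= 100)
  # two-sample edge case and the single-class error
  two <- epoched_recording(ds$data[, , 1:2], ds$fs, ds$channels, ds$classes[1:2])
  cv2 <- loocv(two, cfg)
  expect_equal(cv2$n, 2L)
  one_class <- epoched_recording(ds$data[, , c(1, 3)], ds$fs, ds$channels,
                                 c("familiar", "familiar"))
  expect_error(loocv(one_class, cfg), class = "snnerp_input_error")
})

test_that("cross-validation results are invariant to sample order", {
  tpl <- high_snr_template()
  ds <- simulate_dataset(n_participants = 1, template = tpl, seed = 5)
  cfg <- synthetic_study_config(resolution = 25)
  cv <- loocv(ds, cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  dsp <- epoched_recording(ds$data[, , perm], ds$fs, ds$channels,
                           ds$classes[perm])
  cvp <- loocv(dsp, cfg)
  expect_equal(cv$confusion, cvp$confusion)
  expect_equal(cv$predictions$predicted[perm], cvp$predictions$predicted)
})

test_that("grid search evaluates every combination and returns the best", {
  tpl <- high_snr_template()
  ds <- simulate_dataset(n_participants = 1, template = tpl, seed = 3)
  ds4 <- epoched_recording(ds$data[, , 1:4], ds$fs, ds$channels, ds$classes[1:4])
  cfg <- synthetic_study_config(resolution = 25)
  g <- param_grid(rate = c(0.01, 0.02), threshold = c(0.18, 0.18),
                  mod = c(0.9, 0.9), n_steps = c(2, 1, 1))
  gs <- grid_search(ds4, g, cfg)
  expect_equal(nrow(gs$results), 2L)
  expect_equal(dim(gs$fold_correct), c(2L, 4L))
  expect_true(all(gs$fold_correct %in% 0:1))
  expect_true(gs$best$rate %in% g$rate)
  single <- grid_search(ds4, param_grid(rate = c(0.01, 0.01),
                                        threshold = c(0.18, 0.18),
                                        mod = c(0.9, 0.9), n_steps = 1), cfg)
  expect_equal(nrow(single$results), 1L)
  expect_equal(single$best, list(rate = 0.01, threshold = 0.18, mod = 0.9))
  expect_error(grid_search(ds4, g[0, ], cfg), class = "snnerp_input_error")
})

test_that("nested cross-validation selects per outer fold", {
  tpl <- high_snr_template()
  ds <- simulate_dataset(n_participants = 1, template = tpl, seed = 3)
  ds4 <- epoched_recording(ds$data[, , 1:4], ds$fs, ds$channels, ds$classes[1:4])
  cfg <- synthetic_study_config(resolution = 25)
  g <- param_grid(rate = c(0.01, 0.02), threshold = c(0.18, 0.18),
                  mod = c(0.9, 0.9), n_steps = c(2, 1, 1))
  gs <- grid_search(ds4, g, cfg, method = "nested")
  expect_equal(nrow(gs$outer), 4L)
  expect_true(all(gs$outer$correct %in% 0:1))
  expect_true(gs$accuracy >= 0 && gs$accuracy <= 100)
})
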
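# Independent slow reference implementations used as oracles.
# These are literal transliterations of the stated update rules, written
# without reference to the package's compiled code paths.

# Naive threshold-based (delta) encoder: baseline V(1) = S(1); at each t
# emit +1 / -1 when S(t) crosses V +/- theta (ties emit) and move V.
tbr_reference <- function(s, theta) {
  v <- s[1]
  idx <- integer(0)
  pol <- integer(0)
  for (t in seq_along(s)[-1]) {
    if (s[t] >= v + theta) {
      idx <- c(idx, t); pol <- c(pol, 1L); v <- v + theta
    } else if (s[t] <= v - theta) {
      idx <- c(idx, t); pol <- c(pol, -1L); v <- v - theta
    }
  }
  data.frame(sample_index = idx, polarity = pol)
}

# Reference LIF + nearest-spike STDP simulator, plain R, edge-by-edge.
# Same contract as the compiled core: one-step synaptic delay, refractory
# neurons skip integration, dt measured in steps, simultaneous pre/post
# fire = depression at dt = 0, one update per incident edge per step.
lif_stdp_reference <- function(n_neurons, edges, events, n_steps,
                               theta_fire, decay, refractory,
                               learn, rate, a_plus, a_minus,
                               tau_plus, tau_minus, w_min, w_max) {
  w <- edges$weight
  pot <- numeric(n_neurons)
  refr <- integer(n_neurons)
  last <- rep(-1L, n_neurons)
  fired_prev <- integer(0)
  sp <- list()
  counts <- integer(n_neurons)
  for (t in seq_len(n_steps)) {
    cur <- numeric(n_neurons)
    for (i in fired_prev) {
      out <- which(edges$pre == i)
      for (e in out) cur[edges$post[e]] <- cur[edges$post[e]] + w[e]
    }
    ev <- events[events$step == t, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      cur[ev$neuron[k]] <- cur[ev$neuron[k]] + ev$amp[k]
    }
    fired_now <- integer(0)
    for (i in seq_len(n_neurons)) {
      if (refr[i] > 0) {
        refr[i] <- refr[i] - 1L
        pot[i] <- 0
        next
      }
      pot[i] <- pot[i] * decay + cur[i]
      if (pot[i] >= theta_fire) {
        pot[i] <- 0
        refr[i] <- refractory
        fired_now <- c(fired_now, i)
        counts[i] <- counts[i] + 1L
        sp[[length(sp) + 1L]] <- c(t, i)
      }
    }
    if (learn && length(fired_now) > 0) {
      for (e in seq_len(nrow(edges))) {
        i <- edges$pre[e]; j <- edges$post[e]
        pre_f <- i %in% fired_now
        post_f <- j %in% fired_now
        dw <- NULL
        if (pre_f && post_f) {
          dw <- -rate * a_minus
        } else if (pre_f) {
          if (last[j] >= 0) dw <- -rate * a_minus * exp(-(t - last[j]) / tau_minus)
        } else if (post_f) {
          if (last[i] >= 0) dw <- rate * a_plus * exp((last[i] - t) / tau_plus)
        }
        if (!is.null(dw)) w[e] <- min(w_max, max(w_min, w[e] + dw))
      }
    }
    last[fired_now] <- t
    fired_prev <- fired_now
  }
  spikes <- if (length(sp) == 0) {
    matrix(0L, 0, 2, dimnames = list(NULL, c("step", "neuron")))
  } else {
    m <- do.call(rbind, sp); colnames(m) <- c("step", "neuron"); m
  }
  list(w = w, spikes = spikes, counts = counts)
}

# Brute-force confusion metrics from per-sample labels (positive = first
# level), tallied sample by sample.
metrics_reference <- function(real, pred, positive) {
  tp <- fn <- fp <- tn <- 0L
  for (k in seq_along(real)) {
    if (real[k] == positive) {
      if (pred[k] == positive) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[k] == positive) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(accuracy = 100 * (tp + tn) / length(real),
       sensitivity = 100 * sens,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       f_score = if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
         100 * 2 * prec * sens / (prec + sens) else NA_real_)
}

# Small random reservoir instance shared by the equivalence tests
random_instance <- function(seed, n_neurons = 12, n_steps = 40,
                            p_edge = 0.25, n_inputs = 3) {
  set.seed(seed)
  pairs <- expand.grid(pre = seq_len(n_neurons), post = seq_len(n_neurons))
  pairs <- pairs[pairs$pre != pairs$post, ]
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, ]
  edges$weight <- runif(nrow(edges), -0.5, 0.8)
  rownames(edges) <- NULL
  n_ev <- rpois(1, 2 * n_steps)
  events <- data.frame(step = sample.int(n_steps, n_ev, replace = TRUE),
                       neuron = sample.int(n_inputs, n_ev, replace = TRUE),
                       amp = sample(c(1, -1), n_ev, replace = TRUE,
                                    prob = c(0.8, 0.2)))
  events <- events[order(events$step), ]
  list(edges = edges, events = events, n_neurons = n_neurons,
       n_steps = n_steps)
}

# Tiny epoched recording for fast IO / pipeline tests
tiny_recording <- function(n_epochs = 4, n_samples = 30, fs = 256,
                           channels = c("O1", "O2", "PZ"), seed = 1) {
  set.seed(seed)
  data <- array(rnorm(length(channels) * n_samples * n_epochs),
                dim = c(length(channels), n_samples, n_epochs))
  epoched_recording(data, fs = fs, channels = channels,
                    classes = rep(c("familiar", "unfamiliar"),
                                  length.out = n_epochs))
}

# The documented high signal-to-noise generator setting
high_snr_template <- function() erp_template_spec(noise_sd = 0.1, pink_sd = 0.1)
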
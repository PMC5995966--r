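#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Threshold-based representation (delta) encoder.
// Baseline tracks the signal in steps of +/- theta; a spike is emitted on
// every crossing (ties emit). Sample indices are 1-based; no spike at t = 1.
// [[Rcpp::export]]
List tbr_encode_cpp(const NumericVector s, const double theta) {
  std::vector<int> idx;
  std::vector<int> pol;
  const int n = s.size();
  double v = s[0];
  for (int t = 1; t < n; ++t) {
    if (s[t] >= v + theta) {
      idx.push_back(t + 1);
      pol.push_back(1);
      v += theta;
    } else if (s[t] <= v - theta) {
      idx.push_back(t + 1);
      pol.push_back(-1);
      v -= theta;
    }
  }
  return List::create(_["sample_index"] = wrap(idx),
                      _["polarity"] = wrap(pol));
}

// Leaky integrate-and-fire reservoir with online nearest-spike STDP.
//
// Per step t = 1..n_steps:
//   1. current = sum of weights from neurons fired at t-1 (one-step synaptic
//      delay) plus external input events scheduled for t (signed amplitudes);
//   2. refractory neurons skip integration (potential held at 0, counter
//      decremented, cannot fire this step);
//   3. others: P <- P * decay + current; fire when P >= theta_fire, then
//      reset to 0 and enter refractory;
//   4. if learning, every synapse with a fired endpoint gets one STDP update
//      against the most recent opposite-side spike time (dt in steps; both
//      endpoints fired together => dt = 0, depression branch), clipped to
//      [w_min, w_max]. Input-event delivery itself is not a reservoir spike.
//
// Neuron indices in `pre`, `post`, `ev_neuron` are 0-based; input events must
// be sorted by step. tau_plus / tau_minus are in steps.
// [[Rcpp::export]]
List lif_stdp_run_cpp(const int n_neurons,
                      const IntegerVector pre, const IntegerVector post,
                      const NumericVector w0,
                      const IntegerVector ev_step,
                      const IntegerVector ev_neuron,
                      const NumericVector ev_amp,
                      const int n_steps,
                      const double theta_fire, const double decay,
                      const int refractory,
                      const bool learn, const double rate,
                      const double a_plus, const double a_minus,
                      const double tau_plus, const double tau_minus,
                      const double w_min, const double w_max) {
  const int n_edges = pre.size();
  NumericVector w = clone(w0);

  // CSR adjacency by pre (outgoing) and by post (incoming), holding edge ids
  std::vector<int> out_ptr(n_neurons + 1, 0), in_ptr(n_neurons + 1, 0);
  for (int e = 0; e < n_edges; ++e) {
    out_ptr[pre[e] + 1]++;
    in_ptr[post[e] + 1]++;
  }
  for (int i = 0; i < n_neurons; ++i) {
    out_ptr[i + 1] += out_ptr[i];
    in_ptr[i + 1] += in_ptr[i];
  }
  std::vector<int> out_idx(n_edges), in_idx(n_edges);
  {
    std::vector<int> o(out_ptr.begin(), out_ptr.end());
    std::vector<int> q(in_ptr.begin(), in_ptr.end());
    for (int e = 0; e < n_edges; ++e) {
      out_idx[o[pre[e]]++] = e;
      in_idx[q[post[e]]++] = e;
    }
  }

  std::vector<double> pot(n_neurons, 0.0), cur(n_neurons, 0.0);
  std::vector<int> refr(n_neurons, 0), last_spike(n_neurons, -1);
  std::vector<char> fired_flag(n_neurons, 0);
  std::vector<int> fired_prev, fired_now;
  std::vector<int> sp_step, sp_neuron;
  IntegerVector counts(n_neurons);

  int ev_i = 0;
  const int n_events = ev_step.size();

  for (int t = 1; t <= n_steps; ++t) {
    std::fill(cur.begin(), cur.end(), 0.0);
    for (size_t k = 0; k < fired_prev.size(); ++k) {
      const int i = fired_prev[k];
      for (int a = out_ptr[i]; a < out_ptr[i + 1]; ++a) {
        const int e = out_idx[a];
        cur[post[e]] += w[e];
      }
    }
    while (ev_i < n_events && ev_step[ev_i] == t) {
      cur[ev_neuron[ev_i]] += ev_amp[ev_i];
      ++ev_i;
    }

    fired_now.clear();
    for (int i = 0; i < n_neurons; ++i) {
      if (refr[i] > 0) {
        refr[i]--;
        pot[i] = 0.0;
        continue;
      }
      pot[i] = pot[i] * decay + cur[i];
      if (pot[i] >= theta_fire) {
        pot[i] = 0.0;
        refr[i] = refractory;
        fired_now.push_back(i);
        fired_flag[i] = 1;
        sp_step.push_back(t);
        sp_neuron.push_back(i + 1);
        counts[i]++;
      }
    }

    if (learn && !fired_now.empty()) {
      for (size_t k = 0; k < fired_now.size(); ++k) {
        const int i = fired_now[k];
        // i as pre-synaptic: pre spike at t, post spike earlier => dt >= 0
        for (int a = out_ptr[i]; a < out_ptr[i + 1]; ++a) {
          const int e = out_idx[a];
          const int j = post[e];
          double dw;
          if (fired_flag[j]) {
            dw = -rate * a_minus; // simultaneous: dt = 0, handled once here
          } else if (last_spike[j] >= 0) {
            const double dt = (double)(t - last_spike[j]);
            dw = -rate * a_minus * std::exp(-dt / tau_minus);
          } else {
            continue;
          }
          w[e] = std::min(w_max, std::max(w_min, w[e] + dw));
        }
        // i as post-synaptic: pre spiked earlier => dt < 0, potentiation
        for (int a = in_ptr[i]; a < in_ptr[i + 1]; ++a) {
          const int e = in_idx[a];
          const int j = pre[e];
          if (fired_flag[j]) continue; // dt = 0 already applied above
          if (last_spike[j] < 0) continue;
          const double dt = (double)(last_spike[j] - t);
          const double dw = rate * a_plus * std::exp(dt / tau_plus);
          w[e] = std::min(w_max, std::max(w_min, w[e] + dw));
        }
      }
    }

    for (size_t k = 0; k < fired_now.size(); ++k) {
      last_spike[fired_now[k]] = t;
      fired_flag[fired_now[k]] = 0;
    }
    fired_prev = fired_now;
  }

  return List::create(_["w"] = w,
                      _["spike_step"] = wrap(sp_step),
                      _["spike_neuron"] = wrap(sp_neuron),
                      _["counts"] = counts);
}
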
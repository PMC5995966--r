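seed: 1
data:
  n_participants: 20
  mode: block_average
  fs: 256.0
  window_ms:
  - 0.0
  - 200.0
paradigm:
  n_blocks: 3
  target_reps: 28
  n_nontarget_logos: 8
  nontarget_reps: 14
  stim_duration_ms: 200.0
  isi_range_ms:
  - 1300.0
  - 1500.0
  familiar_fraction: 0.5
template:
  noise_sd: 2.0
  pink_sd: 2.0
  pink_exponent: 1.0
tbr:
  theta: ~
  k: 0.5
  per_channel: yes
small_world:
  radius: 2
  p0: 0.9
  decay: 2.2
  pos_fraction: 0.8
  w_init_max: 0.1
lif:
  theta_fire: 0.5
  tau_leak_ms: 10.0
  refractory_steps: 1
stdp:
  rate: 0.01
  a_plus: 1.0
  a_minus: 1.0
  tau_plus_ms: 10.0
  tau_minus_ms: 10.0
  w_min: -1.0
  w_max: 1.0
desnn:
  mod: 0.4
  drift: 0.005
  drift_decay: no
  mode: weight_similarity
grid:
  rate:
  - 0.001
  - 0.1
  threshold:
  - 0.1
  - 1.0
  mod:
  - 0.1
  - 0.9
  n_steps: 10
pipeline:
  resolution: 12.0
  passes: 1
  frame_ms: 50.0
  input_gain: 1.0
  negative_input: signed
  init_seed: 42
package_version: 0.1.0
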
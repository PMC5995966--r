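# Small demonstration profile: two simulated participants (12 samples),
# a coarse 25 mm lattice (~180 neurons) and the synthetic-study parameters,
# so the full evaluate path finishes in well under a minute.
seed: 1
data:
  n_participants: 2
  mode: block_average
template:
  noise_sd: 0.1
  pink_sd: 0.1
lif:
  theta_fire: 0.18
  tau_leak_ms: 30
desnn:
  mod: 0.9
  drift: 0.3
grid:
  n_steps: 2
pipeline:
  resolution: 25
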
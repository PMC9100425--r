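# Example afmflex run configuration (all keys optional; defaults documented
# in ?run_config). Lengths in nm, temperature in K, masks are 1-based
# inclusive pixel indices on the uncropped frame.
k_bias: 300
sigma_x: 0.5
sigma_y: 0.5
gamma: 0.1
temperature: 300
n_steps: 200000
dt: 0.3
n_replicas: 3
seed: 1
record_interval: 1000
fit_mask:  {x_first: 26, x_last: 65, y_first: 1, y_last: 30}
neck_mask: {x_first: 33, x_last: 57, y_first: 12, y_last: 23}
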
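scenario: fishing_down_three_level
n_levels: 3
harvest_level: 3
f: 0.0077
f_error_cv: 0.05
evolve:
- 1
- 2
tradeoffs:
  '1':
    A: 20.5
    V: 48.8
  '2':
    A: 17.0
    V: 58.8
burn_in: 20000
harvest_iters: 20000
replicates: 12
base_seed: 1
phase_scale: 1.0
pop_scale: 1.0
rate_scale: 100.0
resource:
  R_max: 24500.0
  r: 0.5
  graze_scale: 0.4
founder:
  mean: 0.0
  sd: 0.25
mutation:
  prob: 0.12
  sd: 0.05
init_sizes:
- 3500
- 420
- 550

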
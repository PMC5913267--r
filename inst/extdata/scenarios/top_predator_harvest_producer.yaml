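scenario: top_predator_harvest_producer
n_levels: 4
harvest_level: 4
f: 0.0009
f_error_cv: 0.05
evolve:
- 1
tradeoffs:
  '1':
    A: 29.5
    V: 39.3
  '2':
    A: 22.0
    V: 45.4
  '3':
    A: 19.1
    V: 52.5
burn_in: 12500
harvest_iters: 12500
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
- 1850
- 1130
- 210
- 140

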
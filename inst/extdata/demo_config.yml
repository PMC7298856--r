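# Demo configuration: a small fully synthetic end-to-end run.
# Analysis parameters follow the study defaults (22 km thinning, 50/50
# split, 200 km accessible-area buffer, r >= 0.80 collinearity filter,
# E = 0.05, 60% ensemble agreement, 10 bootstrap replicates); the problem
# size (grid, ensemble, candidate grid) is reduced so the demo finishes in
# a few minutes on one CPU.
seed: 7
n_occurrences: 400
d_km: 22
fraction: 0.5
B_km: 200
r_max: 0.80
min_size: 2
rms: [1]
class_subsets: ["lq"]
E: 0.05
alpha: 0.05
n_boot: 10
cutoff_frac: 0.6
mop_reference_fraction: 0.1
mop_sample_cap: 2000
proc_iterations: 200
proc_fraction: 0.5
bg_max: 5000
knots: 10
max_sets: 5
strong_only: true
flag_cutoff: 10
breakpoints: [0, 1, 5, 10, 20, 50, 100]
synthetic:
  nrow: 60
  ncol: 60
  cellsize: 0.2
  xll: -60
  yll: -25
  n_layers: 7
  correlation: 0.3
  n_gcm: 5
  n_regions: 4
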
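# Sweep specification for the CLI `sweep` subcommand: membrane-separation
# dependence of the mean translocation time, fitted over R in [2, 10].
vary: r_sep
grid: [2, 3, 4, 6, 8, 10, 12, 15]
n_samples: 100
base_seed: 1
fit_range: [2, 10]
params:
  n_bonds: 25
  kappa: 10
  e_field: 2.5
  relax_window: 500
  max_mcs: 1.0e6
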
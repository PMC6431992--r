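# Desk-scale run configuration: short chain in a R = 5 slab.
# Missing keys take the reference defaults; unknown keys are rejected.
n_bonds: 25
kappa: 10
e_field: 5
r_sep: 5
n_samples: 100
base_seed: 1
relax_window: 500
max_mcs: 1.0e6
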
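# Secondary tauopathy on the synthetic channel lattice: toxic amyloid
# seeded on the left face, a negligible toxic-tau inoculum everywhere.
# Toxic tau ignites only behind the amyloid front and saturates at the
# fully toxic level 7/12 = 0.583...
graph:
  lattice: [30, 6, 3]
params: secondary_table1
seeds:
  - species: ut
    amount: 0.05
    x_max: 4
  - species: vt
    amount: 1.0e-11
    x_max: 29
t_end: 400
n_out: 101
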
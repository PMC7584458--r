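# Primary tauopathy on the synthetic 30 x 6 x 3 channel lattice:
# toxic amyloid seeded on the left face, toxic tau on the right face.
# The two fronts propagate, collide, and the tau field steps up from the
# amyloid-free plateau (0.25) to the fully toxic level (0.45).
graph:
  lattice: [30, 6, 3]
params: primary_table1
seeds:
  - species: ut
    amount: 0.05
    x_max: 4
  - species: vt
    amount: 0.05
    x_min: 25
damage:
  k1: 1.0e-4
  k2: 1.0e-2
  k3: 1.0e-1
  k4: 1.0e-3
t_end: 150
n_out: 76
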
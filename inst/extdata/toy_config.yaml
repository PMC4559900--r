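paths:
  alignment: ~
  alignment_format: fasta
  structure: ~
  chain: ~
  mapping_table: ~
  native_dimer: ~
synth:
  enabled: yes
  'n': 30
  interface_size: 8
  q: 8
  beta: 2.0
  J0: 1.0
  M: 2000
  burn_in: 200
  thin: 10
dca:
  theta: 0.8
  lambda: ~
  min_separation: 2
filter:
  sasa_threshold: 0.0
  n_top: 100
  monomer_cutoff: 8.0
  dilation: 0.0
  sasa_probe: 1.4
  sasa_n_points: 960
sbm:
  k_b: 200.0
  k_a: 40.0
  k_d_base: 1.0
  kd_factor: 100.0
  sigma_ex: 4.0
  epsilon: 1.0
  contact_cutoff: 8.0
  contact_min_sep: 4.0
  A_intra: 1.0
  w_intra: 0.5
schedule:
  stage:
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  r0:
  - 50.0
  - 38.0
  - 28.0
  - 20.0
  - 14.0
  - 10.0
  - 8.0
  A:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  w:
  - 10.0
  - 8.0
  - 6.0
  - 5.0
  - 4.0
  - 3.0
  - 1.5
  max_steps:
  - 100000
  - 100000
  - 100000
  - 100000
  - 100000
  - 100000
  - 100000
  window:
  - 200
  - 200
  - 200
  - 200
  - 200
  - 200
  - 200
  tol:
  - 0.02
  - 0.02
  - 0.02
  - 0.02
  - 0.02
  - 0.02
  - 0.02
simulate:
  dt: 0.002
  gamma: 0.05
  temperature: 0.5
  stride: 100
  separation: 50.0
  angle_deg: 180.0
evaluate:
  interface_cutoff: 10.0
  contact_cutoff: 8.0
seed: 3
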
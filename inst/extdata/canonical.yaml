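# Canonical parameter set: von Bertalanffy growth a=0.7, b=0.5,
# alpha=0.85, beta=1 with doubling-period exponent xi=0.15; sloppy size
# control with threshold 0.7, rate shape 4*(x-0.7)^2/(1-x) and daughter
# sizes uniform on [0.4, 0.6] of the parent; constant background
# mortality 0.1; unit-yield chemostat.
growth:
  a_inf: 0.7
  b: 0.5
  alpha: 0.85
  beta: 1.0
  xi: 0.15
  r: 1.0
division:
  xth: 0.7
  delta: 0.2
  k_shape: quadratic_pole
  q_shape: uniform
  k_scale: 4.0
  idealised: false
mortality:
  m0: 0.1
predation:
  nu: 0.85
  epsilon: 0.3
  ratio_mode: 100.0
  log_width: 1.0
  s0: 1.0
chemostat:
  rho0: 1.0
  N0: 10.0
  theta: 1.0
assemblage:
  n_species: 16
  w_min: 1.0
  w_max: 1000.0
run:
  seed: 1
  n_grid: 512
  n_cells: 256
  t_end: 100.0
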
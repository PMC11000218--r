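# Example pipeline configuration (reduced units, toy model system)
model_system:
  kind: radial_binding_2d
  depth: 6
  barrier: 2
cvs:
  cn_r0: 1.4
  cn_m: 6
  cn_n: 12
  cn_cmax: 1.0
  wall_k: 10.0
  wall_rho_s: 4.2
  monitor_threshold: 0.01
langevin:
  timestep: 0.0005
  friction: 1.0
  kT: 1.0
  n_steps: 400000
  seed: 1
  save_stride: 200
metad:
  height: 0.5
  stride: 0.5
  sigma:
    rho: 0.2
  bias_factor: 10
kinetics:
  n_runs: 41
  horizon: 200
thermo:
  temperature: 300
  rho_s: 28
  v_prot: 48300
  v0: 1660
  c0: 1
  dg_metad: -3.3
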
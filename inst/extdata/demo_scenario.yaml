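# Demo configuration: desk-scale fertility-transition run on the bundled
# synthetic schedules (cmd_simulate with no schedule files).
scenario:
  start_year: 1980
  end_year: 2010
  burnin_years: 35
  population_size: 20000
  n_replicates: 10
  seed: 1
  sp_mode: annual_redraw
  tech_mode: absorbing
params:
  gamma: 0.2
  alpha: 0.075
  sigma: 1.7
  beta: 0.2
  rho: 0.5
  phi: 7
calibration:
  n_points: 224
  n_replicated: 44
  reps: 5
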
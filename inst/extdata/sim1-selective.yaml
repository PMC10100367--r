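# One A-type group invading an S-type metapopulation under selective
# migration with abundant nutrients (run with: ecoscaffold sim1 --config ...)
experiment: sim1
params:
  R_in: 50
  delta: 0.98
  P_mut: 1.0e-6
dispersal:
  mode: SM
  delta_g: 100
run:
  seed: 1
  n_trials: 100
  n_gens: 20000
  outdir: results
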
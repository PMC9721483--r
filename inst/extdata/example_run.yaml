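# Minimal run configuration: score a user-supplied (rational) design on the
# built-in chemostat model. Other tasks: design_osao, design_mpc, train_fq,
# train_rt3d, eval_inference.
task: design_rational
seed: 1
design_file: inst/extdata/staircase_design.csv
n_steps: 10
step_duration: 2
model:
  mu_max: 1
  K0: 6.8e-5
  K1: 4.9e-4
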
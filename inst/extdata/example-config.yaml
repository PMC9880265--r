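# Example run configuration for run_experiment() / the CLI script.
experiment: consolidate
seed: 1
N: 100
patterns: 100
mc_runs: 1000
profile: none
device:
  preset: default      # or gamma1 / gamma2 / stochastic_low, or explicit
  # dt_pulse: 0.25     # fields of fn_device() override the preset
out_dir: results
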
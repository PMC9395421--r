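# Three-flash staircase: generate a synthetic wild-type experiment and the
# matching ground truth (analyze it with analyze_steps.yaml afterwards).
command: make-synthetic
preset: rvx_wt
seed: 42
output: results/rvx_wt_flash
protocol:
  mode: flash_train
  duration: 1.6e-3
  flash_times: [2.0e-4, 6.0e-4, 1.0e-3]
  sampling: 5.0e-5
noise:
  sigma: 1.0e-4
  n_averages: 32
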
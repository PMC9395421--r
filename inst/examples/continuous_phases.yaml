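# Continuous strong illumination: synthesize a three-phase accumulation
# trace; analyze it with command analyze-phases on the written CSV.
command: make-synthetic
preset: rvx_wt
seed: 42
output: results/rvx_wt_continuous
protocol:
  mode: continuous
  duration: 3.0e-2
  sampling: 5.0e-5
noise:
  sigma: 1.0e-4
  n_averages: 32
options:
  k_L: 1.5e4
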
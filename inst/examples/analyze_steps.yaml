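# Reduce a flash-train trace to step heights and donor equilibrium
# constants (run flash_steps.yaml first to create the input).
command: analyze-steps
input: results/rvx_wt_flash.csv
output: results/rvx_wt_kd
options:
  window: [1.0e-4, 3.5e-4]
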
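# Ferricyanide titration: simulate progressive pool oxidation over two
# hours and recover the declining donor equilibrium constants.
command: titrate
preset: rvx_wt
seed: 42
output: results/rvx_wt_titration
options:
  t_inc: [0, 1200, 2400, 3600, 4800, 6000, 7200]
  clip_tol: 0.05
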
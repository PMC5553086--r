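# Main effects only: null for pure-interaction tests
preset: main_effects
label: main effects only, MAF 0.4
params:
  maf: 0.4
  beta: 0.4
  replicates: 1000
  seed: 1
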
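# Low MAF with LD calibrated to control r2 = 0.24 (combined emerges ~0.29)
preset: low_maf_ld
label: MAF 0.1, control r2 0.24, allelic effects
params:
  maf: 0.1
  target_r2: 0.24
  replicates: 1000
  seed: 1
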
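# Very low MAF, strong LD, complex (non-allelic) per-genotype log odds
preset: rare_ld_complex
label: control MAF 0.01, control r2 0.64, complex effects
params:
  maf: 0.01
  target_r2: 0.64
  case_maf: 0.03
  replicates: 1000
  seed: 1
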
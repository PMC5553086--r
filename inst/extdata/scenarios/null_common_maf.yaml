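# Type-I error arm: common MAF, no LD, no genotype effect
preset: null
label: null, MAF 0.4, no LD, 5000 replicates
params:
  maf: 0.4
  replicates: 5000
  seed: 1
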
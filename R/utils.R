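# internal helpers

# deterministic sub-seed: keeps every derived seed in [1, 2^31 - 2] and
# within exact double-precision integer range during the arithmetic
derive_seed <- function(root, index) {
  as.integer((((root %% 2147483647) * 69069 + index * 7907) %% 2147483646) + 1)
}

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))
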
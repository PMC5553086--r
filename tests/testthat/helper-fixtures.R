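# shared fixtures, built in code

# a well-filled 2 x 9 table (all 18 cells positive)
full_table <- function(seed = 42) {
  set.seed(seed)
  pair_table(cases = sample(5:40, 9, replace = TRUE),
             controls = sample(5:40, 9, replace = TRUE))
}

# one null replicate at common MAF: two independent SNPs, random phenotype
null_replicate <- function(n = 1000, maf = 0.4, seed = 1) {
  set.seed(seed)
  list(geno1 = rbinom(n, 2, maf),
       geno2 = rbinom(n, 2, maf),
       phenotype = sample(rep(c(1L, 0L), c(n / 2, n / 2))))
}

null_table <- function(n = 1000, maf = 0.4, seed = 1) {
  d <- null_replicate(n, maf, seed)
  build_table(d$geno1, d$geno2, d$phenotype)
}

# brute-force Pearson X2 over a counts matrix, double loop over cells
pearson_oracle <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  x2 <- 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      e <- rs[i] * cs[j] / N
      x2 <- x2 + (counts[i, j] - e)^2 / e
    }
  unname(x2)
}

# deviance G2 of a 2 x k counts matrix against independence
g2_oracle <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  g2 <- 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      o <- counts[i, j]
      if (o > 0) g2 <- g2 + 2 * o * log(o / (rs[i] * cs[j] / N))
    }
  unname(g2)
}
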
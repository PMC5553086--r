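test_that("solve_haplotypes hits the target r-squared analytically", {
  hap <- solve_haplotypes(0.1, 0.1, 0.24)
  expect_equal(hap$D, sqrt(0.24) * 0.09, tolerance = 1e-12)
  expect_equal(unname(hap$freqs[1]), 0.1 * 0.1 + sqrt(0.24) * 0.09,
               tolerance = 1e-12)
  expect_equal(hap$r2, 0.24, tolerance = 1e-12)
  expect_equal(hap$maf1, 0.1, tolerance = 1e-12)

  # r2 = 0 gives product frequencies
  hap0 <- solve_haplotypes(0.4, 0.4, 0)
  expect_equal(unname(hap0$freqs[1]), 0.16, tolerance = 1e-12)
  expect_equal(hap0$D, 0)

  # a sweep of feasible targets round-trips through the derived field
  for (r2 in c(0.05, 0.3, 0.6, 0.75))
    expect_equal(solve_haplotypes(0.3, 0.25, r2)$r2, r2, tolerance = 1e-12)
})

test_that("infeasible LD targets error with the feasible range", {
  expect_error(solve_haplotypes(0.01, 0.5, 0.9), "feasible")
})

test_that("genotype distribution factorises without LD and degenerates at r2 = 1-", {
  # independence: outer product of single-locus HWE vectors
  hap <- solve_haplotypes(0.5, 0.5, 0)
  gp <- genotype_distribution(hap)
  expect_equal(sum(gp), 1, tolerance = 1e-12)
  expect_equal(gp[5], 0.25, tolerance = 1e-12)  # het x het
  hwe <- function(m) c((1 - m)^2, 2 * m * (1 - m), m^2)
  hap2 <- solve_haplotypes(0.3, 0.2, 0)
  expect_equal(genotype_distribution(hap2),
               as.vector(t(outer(hwe(0.3), hwe(0.2), "*"))),
               tolerance = 1e-12)
  # near-perfect LD at equal MAFs: only concordant genotype pairs survive
  hap3 <- solve_haplotypes(0.2, 0.2, 0.999999)
  gp3 <- genotype_distribution(hap3)
  discordant <- setdiff(1:9, c(1, 5, 9))
  expect_lt(sum(gp3[discordant]), 1e-5)
})

test_that("retrospective distributions obey total probability and enrich risk alleles", {
  hap <- solve_haplotypes(0.2, 0.2, 0.1)
  gp <- genotype_distribution(hap)
  pen <- penetrance_logit_linear(-2, 0.5, 0.3, 0.2)
  ccd <- case_control_distributions(gp, pen)
  expect_equal(sum(ccd$case), 1, tolerance = 1e-12)
  expect_equal(sum(ccd$control), 1, tolerance = 1e-12)
  mix <- ccd$prevalence * ccd$case + (1 - ccd$prevalence) * ccd$control
  expect_equal(mix, gp, tolerance = 1e-12)
  expect_gt(ccd$maf["case", 1], ccd$maf["control", 1])
  expect_gt(ccd$maf["case", 2], ccd$maf["control", 2])

  # constant penetrance: case and control distributions equal the population
  null_ccd <- case_control_distributions(gp, penetrance_logit_linear(-2))
  expect_equal(null_ccd$case, gp, tolerance = 1e-12)
  expect_equal(null_ccd$control, gp, tolerance = 1e-12)
})

test_that("tabular penetrance covers non-allelic surfaces and is flagged as such", {
  M <- rbind(c(0, 0, 1), c(0, 1, 0.5), c(1, 0.5, 2))
  expect_false(is_allelic_representable(M))
  expect_true(is_allelic_representable(outer(0:2, 0:2) * 0.3 + 0.1))
  pen <- penetrance_table(M - 2)
  pv <- penetrance_vector(pen)
  expect_equal(pv[9], plogis(2 - 2), tolerance = 1e-12)
})

test_that("replicates are deterministic in (seed, index) and have exact sample sizes", {
  scen <- scenario_null(replicates = 3, seed = 99)
  a <- sample_replicate(scen, 2)
  b <- sample_replicate(scen, 2)
  expect_identical(a, b)
  c2 <- sample_replicate(scen, 3)
  expect_false(identical(a$geno1, c2$geno1))
  expect_equal(sum(a$phenotype == 1), 500)
  expect_equal(sum(a$phenotype == 0), 500)
})

test_that("pooled sampled genotype frequencies match the analytic distributions", {
  scen <- scenario_low_maf_ld(n_cases = 2000, n_controls = 2000,
                              replicates = 1, seed = 61)
  nrep <- 25
  pooled_case <- numeric(9); pooled_ctrl <- numeric(9)
  for (r in seq_len(nrep)) {
    d <- sample_replicate(scen, r)
    idx <- 3 * d$geno1 + d$geno2 + 1
    pooled_case <- pooled_case + tabulate(idx[d$phenotype == 1], 9)
    pooled_ctrl <- pooled_ctrl + tabulate(idx[d$phenotype == 0], 9)
  }
  n <- nrep * 2000
  for (cat in 1:9) {
    se_case <- sqrt(scen$dist$case[cat] * (1 - scen$dist$case[cat]) / n)
    expect_lt(abs(pooled_case[cat] / n - scen$dist$case[cat]),
              3 * se_case + 1e-4)
    se_ctrl <- sqrt(scen$dist$control[cat] * (1 - scen$dist$control[cat]) / n)
    expect_lt(abs(pooled_ctrl[cat] / n - scen$dist$control[cat]),
              3 * se_ctrl + 1e-4)
  }
})

test_that("empirical r-squared behaves at the extremes", {
  set.seed(15)
  g <- rbinom(500, 2, 0.3)
  expect_equal(empirical_r2(g, g), 1)
  g2 <- rbinom(50000, 2, 0.3)
  g3 <- rbinom(50000, 2, 0.3)
  expect_lt(empirical_r2(g2, g3), 0.005)
  expect_true(is.na(empirical_r2(rep(1, 10), rbinom(10, 2, 0.5))))
  expect_error(empirical_r2(1, 1), "at least 2")
})

test_that("LR3 maximum likelihood recovers generating allelic coefficients", {
  scen <- scenario_low_maf_ld(n_cases = 1e5, n_controls = 1e5,
                              replicates = 1, seed = 55)
  d <- sample_replicate(scen, 1)
  tab <- build_table(d$geno1, d$geno2, d$phenotype)
  cnt <- tab$counts
  X <- wpair:::.pair_design(c("x1", "x2", "x1:x2"), "allelic_dosage")
  fit <- fit_logistic(X, cbind(cnt[2, ], cnt[1, ]))
  truth <- c(scen$penetrance$beta, scen$penetrance$gamma,
             scen$penetrance$interaction)
  est <- fit$coef[2:4]
  se <- sqrt(diag(fit$vcov))[2:4]
  # retrospective sampling preserves beta, gamma, i (not the intercept)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("scenario objects expose the calibrated conditions", {
  scen <- scenario_rare_ld_complex(seed = 2)
  expect_equal(unname(scen$dist$maf["control", ]), c(0.01, 0.01),
               tolerance = 1e-6)
  expect_equal(wpair:::.dist_r2(scen$dist$control), 0.64, tolerance = 1e-6)
  expect_equal(unname(scen$dist$maf["case", 1]), 0.03, tolerance = 1e-4)
  expect_false(is_allelic_representable(scen$penetrance$log_odds))
})
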
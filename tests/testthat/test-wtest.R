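test_that("cell statistics match the hand-evaluated formulas", {
  # one category with n1 = 10 of N1 = 100, n0 = 5 of N0 = 100; remaining
  # mass lumped into another category so totals come out right
  tab <- pair_table(cases = c(10, 90, rep(0, 7)),
                    controls = c(5, 95, rep(0, 7)))
  cs <- cell_stats(tab)
  expect_equal(cs$k, 2L)
  expect_equal(cs$phat1[1], 0.1)
  expect_equal(cs$phat0[1], 0.05)
  se <- sqrt(1 / 5 + 1 / 10 + 1 / 90 + 1 / 95)
  expect_equal(cs$se[1], se, tolerance = 1e-12)
  expect_equal(se, 0.56713, tolerance = 1e-4)
  expect_equal(cs$z[1], log((0.1 / 0.9) / (0.05 / 0.95)) / se,
               tolerance = 1e-12)
  expect_equal(cs$z[1], 1.3175, tolerance = 1e-4)
})

test_that("equal case/control proportions give a zero z vector", {
  tab <- pair_table(cases = c(10, 20, 30, 40, rep(0, 5)) * 2,
                    controls = c(10, 20, 30, 40, rep(0, 5)))
  cs <- cell_stats(tab)
  expect_equal(cs$z, rep(0, cs$k))
  w <- w_test(tab)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
})

test_that("z is antisymmetric under case/control swap and sum(z^2) invariant", {
  tab <- full_table(seed = 7)
  swapped <- pair_table(cases = tab$counts[1, ], controls = tab$counts[2, ])
  z1 <- cell_stats(tab)$z
  z2 <- cell_stats(swapped)$z
  expect_equal(z2, -z1, tolerance = 1e-12)
  expect_equal(sum(z1^2), sum(z2^2), tolerance = 1e-12)
  expect_equal(w_test(tab)$p_value, w_test(swapped)$p_value,
               tolerance = 1e-12)
})

test_that("cell statistics use full-sample totals after category reduction", {
  # category 1 is empty in controls and gets dropped; N1 must stay 100
  tab <- pair_table(cases = c(4, 48, 48, rep(0, 6)),
                    controls = c(0, 50, 50, rep(0, 6)))
  cs <- cell_stats(tab)
  expect_equal(cs$indices, 2:3)
  expect_equal(cs$phat1, c(48, 48) / 100)
})

test_that("default (h, f) follow the (k-1)/k and k-1 formulas", {
  hf <- default_hf(9)
  expect_equal(hf$h, 8 / 9)
  expect_equal(hf$f, 8)
  expect_equal(hf$source, "default")
  hf2 <- default_hf(2)
  expect_equal(hf2$h, 0.5)
  expect_equal(hf2$f, 1)
  expect_error(default_hf(1), "k must be")
})

test_that("W statistic is h * sum(z^2) with a chi-squared_f tail", {
  tab <- full_table(seed = 9)
  cs <- cell_stats(tab)
  w <- w_statistic(cs, default_hf(cs$k))
  expect_equal(w$statistic, (8 / 9) * sum(cs$z^2), tolerance = 1e-12)
  expect_equal(w$df, 8)
  expect_equal(w$p_value,
               pchisq(w$statistic, df = 8, lower.tail = FALSE))
  # closed form: with h = 1, f = 2 the survival function is exp(-x/2),
  # so sum(z^2) = 2 log(20) gives p = 0.05 exactly
  cs2 <- cs
  cs2$z <- c(sqrt(2 * log(20)), rep(0, cs$k - 1))
  w2 <- w_statistic(cs2, wpair:::hf_params(1, 2, cs$k))
  expect_equal(w2$p_value, 0.05, tolerance = 1e-12)
})

test_that("p-value decreases strictly in the statistic for fixed (h, f)", {
  stats <- seq(0.5, 30, by = 0.5)
  p <- pchisq((8 / 9) * stats, df = 8, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("non-integer degrees of freedom are accepted", {
  tab <- full_table(seed = 10)
  cs <- cell_stats(tab)
  hf <- wpair:::hf_params(0.91, 7.37, cs$k, source = "bootstrap")
  w <- w_statistic(cs, hf)
  expect_true(w$defined)
  expect_equal(w$df, 7.37)
  expect_equal(w$p_value,
               pchisq(0.91 * sum(cs$z^2), df = 7.37, lower.tail = FALSE))
})

test_that("multinomial covariance matches the closed form and simulation", {
  cov2 <- multinomial_covariance(c(0.5, 0.5), 1)
  expect_equal(cov2, matrix(c(0.25, -0.25, -0.25, 0.25), 2))
  probs <- c(0.1, 0.2, 0.3, 0.4)
  cc <- multinomial_covariance(probs, 50)
  expect_equal(diag(cc), probs * (1 - probs) / 50)
  expect_equal(rowSums(cc), rep(0, 4), tolerance = 1e-15)
  expect_error(multinomial_covariance(c(0.5, 0.4), 10), "sum to 1")

  # empirical covariance of phat over multinomial draws matches theory
  set.seed(31)
  N <- 500
  draws <- t(rmultinom(4000, N, probs)) / N
  emp <- cov(draws)
  theo <- multinomial_covariance(probs, N)
  expect_lt(max(abs(emp - theo)), 5e-5)  # ~10x the Monte-Carlo SE
})
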
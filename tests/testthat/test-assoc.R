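test_that("full-table chi-squared matches a brute-force oracle and uses 8 df", {
  for (seed in c(2, 13, 27)) {
    tab <- full_table(seed)
    res <- chisq_full(tab)
    expect_true(res$defined)
    expect_equal(res$df, 8)
    expect_equal(res$statistic, pearson_oracle(tab$counts),
                 tolerance = 1e-12)
    expect_equal(res$p_value,
                 pchisq(res$statistic, 8, lower.tail = FALSE),
                 tolerance = 1e-14)
  }
})

test_that("identical case and control count vectors give X2 = 0, p = 1", {
  v <- c(12, 8, 5, 20, 11, 9, 7, 15, 13)
  res <- chisq_full(pair_table(v, v))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("the full test goes undefined on an empty column while the reduced test adapts", {
  cases <- c(0, rep(12, 8)); controls <- c(0, rep(10, 8))
  tab <- pair_table(cases, controls)
  full <- chisq_full(tab)
  expect_false(full$defined)
  expect_true(is.na(full$p_value))
  red <- chisq_reduced(tab)
  expect_true(red$defined)
  expect_equal(red$df, 7)
  # and with no empty columns the two conventions agree exactly
  tab2 <- full_table(3)
  expect_equal(chisq_full(tab2)$p_value, chisq_reduced(tab2)$p_value,
               tolerance = 0)
  # single-category table: undefined under both
  tab3 <- pair_table(c(50, rep(0, 8)), c(50, rep(0, 8)))
  expect_false(chisq_reduced(tab3)$defined)
})

test_that("chi-squared tests are invariant under case/control swap", {
  tab <- full_table(21)
  sw <- pair_table(cases = tab$counts[1, ], controls = tab$counts[2, ])
  expect_equal(chisq_full(tab)$statistic, chisq_full(sw)$statistic,
               tolerance = 1e-12)
  expect_equal(chisq_reduced(tab)$p_value, chisq_reduced(sw)$p_value,
               tolerance = 1e-12)
})

test_that("intercept-only logistic fit has the closed-form binomial log-likelihood", {
  n1 <- 30; n0 <- 70
  fit <- fit_logistic(matrix(1, 100, 1), rep(c(1, 0), c(n1, n0)))
  expect_equal(fit$loglik, n1 * log(0.3) + n0 * log(0.7), tolerance = 1e-8)
  expect_equal(fit$rank, 1L)
})

test_that("saturated genotypic fit reproduces observed per-category case fractions", {
  tab <- full_table(29)
  cnt <- tab$counts
  y <- cbind(cnt[2, ], cnt[1, ])
  X <- wpair:::.pair_design(c("g1", "g2", "g1:g2"), "genotypic_indicators")
  fit <- fit_logistic(X, y)
  expect_equal(fit$rank, 9L)
  expect_equal(unname(fit$fitted), unname(cnt[2, ] / colSums(cnt)),
               tolerance = 1e-8)
})

test_that("duplicated design columns reduce rank but not the likelihood", {
  set.seed(4)
  X <- cbind(1, rbinom(100, 2, 0.4))
  y <- rbinom(100, 1, 0.5)
  f1 <- fit_logistic(X, y)
  f2 <- fit_logistic(cbind(X, X[, 2]), y)
  expect_equal(f2$rank, f1$rank)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-10)
  expect_true(any(is.na(f2$coef)))
})

test_that("fit_logistic rejects a non-binary response", {
  expect_error(fit_logistic(matrix(1, 3, 1), c(0, 1, 2)), "binary")
})

test_that("LR8 equals the deviance G2 of the table and carries 8 df when full", {
  tab <- full_table(31)
  res <- lr_test(tab, lr_specs()$LR8)
  expect_true(res$defined)
  expect_equal(res$df, 8)
  expect_equal(res$statistic, g2_oracle(tab$counts), tolerance = 1e-6)
  # agrees with Pearson X2 to first order on large balanced counts
  big <- null_table(n = 4000, seed = 8)
  expect_equal(lr_test(big, lr_specs()$LR8)$statistic,
               chisq_full(big)$statistic, tolerance = 0.15)
})

test_that("allelic LR tests have their nominal df on full-rank data", {
  tab <- null_table(seed = 12)
  expect_equal(lr_test(tab, lr_specs()$LR3)$df, 3)
  expect_equal(lr_test(tab, lr_specs()$LR1)$df, 1)
  expect_equal(lr_test(tab, lr_specs()$LRI)$df, 1)
})

test_that("LR statistics are monotone over the nested alternatives", {
  for (seed in c(3, 14, 25)) {
    tab <- null_table(seed = seed)
    s8 <- lr_test(tab, lr_specs()$LR8)$statistic
    s3 <- lr_test(tab, lr_specs()$LR3)$statistic
    s1 <- lr_test(tab, lr_specs()$LR1)$statistic
    expect_gte(s8, s3 - 1e-8)
    expect_gte(s3, s1 - 1e-8)
  }
})

test_that("LR tests drop parameters on structurally sparse tables instead of failing", {
  # only 4 categories present: saturated test df adapts to k' - 1
  cases <- c(10, 5, 0, 8, 3, 0, 0, 0, 0)
  controls <- c(12, 6, 0, 7, 2, 0, 0, 0, 0)
  res <- lr_test(pair_table(cases, controls), lr_specs()$LR8)
  expect_true(res$defined)
  expect_equal(res$df, 3)
  # degenerate: interaction column constant at zero -> 0 df -> undefined
  cases2 <- c(10, 5, 0, 8, 0, 0, 0, 0, 0)
  controls2 <- c(12, 6, 0, 7, 0, 0, 0, 0, 0)
  res2 <- lr_test(pair_table(cases2, controls2), lr_specs()$LRI)
  expect_false(res2$defined)
})

test_that("LR tests go undefined for a degenerate phenotype", {
  tab <- pair_table(rep(0, 9), c(10, 10, 10, rep(0, 6)))
  res <- lr_test(tab, lr_specs()$LR3)
  expect_false(res$defined)
})

test_that("null p-values are close to uniform for every LR spec", {
  set.seed(77)
  n_rep <- 300
  p <- matrix(NA_real_, n_rep, 4,
              dimnames = list(NULL, c("LR8", "LR3", "LR1", "LRI")))
  for (r in seq_len(n_rep)) {
    tab <- null_table(seed = 1000 + r)
    for (s in colnames(p)) p[r, s] <- lr_test(tab, lr_specs()[[s]])$p_value
  }
  for (s in colnames(p)) {
    ks <- suppressWarnings(ks.test(p[, s], "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})
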
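#' Per-category cell statistics for the W-test
#'
#' For each retained genotype category i the case and control frequencies are
#' \eqn{\hat p_{1i} = n_{1i}/N_1} and \eqn{\hat p_{0i} = n_{0i}/N_0}, the
#' standard error is
#' \deqn{SE_i = \sqrt{1/n_{0i} + 1/n_{1i} + 1/(N_0 - n_{0i}) + 1/(N_1 - n_{1i})}}
#' and the normalized log odds ratio is
#' \deqn{z_i = \log\frac{\hat p_{1i}/(1-\hat p_{1i})}{\hat p_{0i}/(1-\hat p_{0i})} / SE_i.}
#' Categories that are empty in cases or controls, or that absorb a full row
#' (n = N, where the SE is undefined), are removed first; `N_0` and `N_1`
#' remain the full-sample totals of the table passed in.
#'
#' @param table a `pair_table` from [build_table()] or [pair_table()].
#' @return A list of class `cell_stats` with vectors `phat1`, `phat0`, `se`,
#'   `z` over the `k` retained categories, the retained column `indices`,
#'   and `k`. `k = 0` (no usable category) is returned as an empty object
#'   rather than an error.
#' @examples
#' tab <- pair_table(cases = c(10, rep(10, 8)), controls = c(5, rep(10, 8)))
#' cell_stats(tab)$z[1]
#' @export
cell_stats <- function(table) {
  stopifnot(inherits(table, "pair_table"))
  red <- observed_columns(table, "any_row_zero")
  N1 <- table$N1; N0 <- table$N0
  if (red$k == 0L)
    return(structure(list(phat1 = numeric(0), phat0 = numeric(0),
                          se = numeric(0), z = numeric(0),
                          indices = integer(0), k = 0L),
                     class = "cell_stats"))
  n0 <- unname(red$table$counts[1L, ]); n1 <- unname(red$table$counts[2L, ])
  phat1 <- n1 / N1; phat0 <- n0 / N0
  se <- sqrt(1 / n0 + 1 / n1 + 1 / (N0 - n0) + 1 / (N1 - n1))
  z <- (log(phat1 / (1 - phat1)) - log(phat0 / (1 - phat0))) / se
  structure(list(phat1 = phat1, phat0 = phat0, se = se, z = z,
                 indices = red$indices, k = red$k),
            class = "cell_stats")
}

#' Default W-test scale and degrees of freedom
#'
#' The default parameterisation for a table with `k` observed categories is
#' scale `h = (k - 1)/k` and degrees of freedom `f = k - 1`.
#'
#' @param k number of observed genotype categories (>= 2).
#' @return An `hf_params` list with `h`, `f`, `k` and `source = "default"`.
#' @export
default_hf <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 2)
    stop("k must be a single integer >= 2")
  k <- as.integer(k)
  structure(list(h = (k - 1) / k, f = k - 1, k = k, source = "default"),
            class = "hf_params")
}

#' @export
print.hf_params <- function(x, ...) {
  cat(sprintf("(h, f) for k = %d: h = %.4f, f = %.4f  [%s]\n",
              x$k, x$h, x$f, x$source))
  invisible(x)
}

hf_params <- function(h, f, k, source = "fixed") {
  if (!is.finite(h) || h <= 0 || !is.finite(f) || f <= 0)
    stop("h and f must be positive and finite")
  structure(list(h = h, f = f, k = as.integer(k), source = source),
            class = "hf_params")
}

#' W statistic and p-value from cell statistics
#'
#' Combines the normalized log odds ratios into the scaled chi-squared
#' statistic \eqn{W = h \sum_i z_i^2}, referred to a chi-squared distribution
#' with (possibly non-integer) `f` degrees of freedom.
#'
#' @param cells a `cell_stats` object.
#' @param hf an `hf_params` object whose `k` matches `length(cells$z)`.
#' @return A `test_result` (see [test_result()]) named `"W"`; undefined when
#'   no category survives reduction (`k < 1`).
#' @export
w_statistic <- function(cells, hf) {
  stopifnot(inherits(cells, "cell_stats"), inherits(hf, "hf_params"))
  if (hf$h <= 0 || hf$f <= 0) stop("h and f must be positive")
  if (cells$k < 1L)
    return(test_result("W", note = "empty reduction"))
  if (hf$k != cells$k)
    stop("hf was derived for k = ", hf$k, " but table has k = ", cells$k)
  stat <- hf$h * sum(cells$z^2)
  test_result("W", statistic = stat, df = hf$f,
              p_value = stats::pchisq(stat, df = hf$f, lower.tail = FALSE))
}

#' The W-test for a two-locus genotype table
#'
#' Convenience wrapper: reduces the table, computes cell statistics, looks up
#' (h, f) and returns the test result.
#'
#' @param table a `pair_table`.
#' @param hf either `NULL` (use [default_hf()] for the observed `k`), a
#'   single `hf_params`, or an `hf_set` from [bootstrap_hf()] /
#'   [read_hf()] keyed by `k`.
#' @return A `test_result`.
#' @examples
#' set.seed(1)
#' g1 <- rbinom(1000, 2, 0.4); g2 <- rbinom(1000, 2, 0.4)
#' w_test(build_table(g1, g2, rep(0:1, each = 500)))
#' @export
w_test <- function(table, hf = NULL) {
  cells <- cell_stats(table)
  if (cells$k < 2L)
    return(test_result("W", note = "fewer than 2 observed categories"))
  use <- if (is.null(hf)) {
    default_hf(cells$k)
  } else if (inherits(hf, "hf_set")) {
    hf_lookup(hf, cells$k)
  } else hf
  w_statistic(cells, use)
}

#' Asymptotic covariance of multinomial category frequencies
#'
#' Returns \eqn{[\mathrm{Diag}(\pi) - \pi\pi^T]/N}, the covariance matrix of
#' the ML frequency estimates \eqn{\hat p_i = n_i/N} for a multinomial sample
#' of size `N` with category probabilities `probs`.
#'
#' @param probs non-negative probabilities summing to 1.
#' @param N sample size (>= 1).
#' @return A `length(probs)` square matrix.
#' @export
multinomial_covariance <- function(probs, N) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be non-negative and sum to 1")
  if (N < 1) stop("N must be >= 1")
  (diag(probs, nrow = length(probs)) - tcrossprod(probs)) / N
}
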
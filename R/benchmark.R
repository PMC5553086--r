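#' Replicate-loop evaluation of type-I error and power
#'
#' Simulates `scen$replicates` data sets, runs every selected test on each,
#' and aggregates rejection rates at level `alpha` under both accounting
#' conventions for undefined results:
#' * `power_defined`: detections / replicates in which the test produced a
#'   result (the 'ignore NA' convention);
#' * `power_total`: detections / all replicates, counting an undefined
#'   result as a non-detection.
#' Under a null scenario the same quantities are read as type-I error.
#' Per-replicate test failures are recorded as undefined, never abort the
#' run.
#'
#' @param scen a `scenario`.
#' @param tests character vector of test names (see [run_tests()]).
#' @param alpha significance level; a result is a detection when
#'   `p <= alpha`.
#' @param hf optional `hf_params`/`hf_set` for the W-test (`NULL` uses the
#'   default (k-1)/k, k-1 parameterisation).
#' @param keep_p return the per-replicate p-value matrix as attribute
#'   `"p_values"` (tests in columns).
#' @return A `power_table` data frame with one row per test: columns
#'   `test`, `n_replicates`, `n_defined`, `n_significant`, `power_defined`,
#'   `power_total`, `alpha`. `power_defined` is `NA` when no replicate gave
#'   a result (0/0), which is distinct from power 0.
#' @examples
#' scen <- scenario_null(replicates = 50, seed = 7)
#' run_scenario(scen, tests = c("W", "CHI-f"), alpha = 0.05)
#' @export
run_scenario <- function(scen, tests = c("W", "CHI-f", "CHI-r", "LR8",
                                         "LR3", "LR1", "LRI"),
                         alpha = 0.05, hf = NULL, keep_p = FALSE) {
  stopifnot(inherits(scen, "scenario"), alpha > 0, alpha < 1)
  R <- scen$replicates
  p <- matrix(NA_real_, R, length(tests), dimnames = list(NULL, tests))
  for (r in seq_len(R)) {
    dat <- sample_replicate(scen, r)
    tab <- tryCatch(build_table(dat$geno1, dat$geno2, dat$phenotype),
                    error = function(e) NULL)
    if (is.null(tab)) next
    res <- lapply(tests, function(t)
      tryCatch(run_tests(tab, t, hf = hf)[[1L]],
               error = function(e) test_result(t, note = conditionMessage(e))))
    p[r, ] <- vapply(res, function(x)
      if (isTRUE(x$defined)) x$p_value else NA_real_, numeric(1))
  }
  n_def <- colSums(!is.na(p))
  n_sig <- colSums(p <= alpha, na.rm = TRUE)
  out <- data.frame(test = tests,
                    n_replicates = R,
                    n_defined = n_def,
                    n_significant = n_sig,
                    power_defined = ifelse(n_def > 0, n_sig / n_def, NA_real_),
                    power_total = n_sig / R,
                    alpha = alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "label") <- scen$label
  attr(out, "seed") <- scen$seed
  if (keep_p) attr(out, "p_values") <- p
  class(out) <- c("power_table", "data.frame")
  out
}

#' Write a power table as delimited text with a metadata header
#'
#' @param pt a `power_table`.
#' @param path output file.
#' @export
write_power_table <- function(pt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario: %s", attr(pt, "label")), con)
  writeLines(sprintf("# seed: %s  alpha: %s", attr(pt, "seed"),
                     unique(pt$alpha)), con)
  utils::write.table(pt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected vs observed quantiles for a Q-Q plot
#'
#' Sorts the observed p-values and pairs rank i of n with the expected
#' uniform quantile `(i - 0.5)/n`, both on the -log10 scale. Undefined
#' (`NA`) p-values are excluded with a message giving the count.
#'
#' @param p_values vector of p-values in (0, 1]; `NA`s allowed.
#' @return Data frame with columns `expected` and `observed`
#'   (-log10 scale), observed ascending in p.
#' @export
qq_data <- function(p_values) {
  n_na <- sum(is.na(p_values))
  if (n_na > 0)
    message(n_na, " undefined p-value(s) excluded from Q-Q data")
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0L) stop("no defined p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p <- sort(p)
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Q-Q plot of observed against expected -log10 p-values
#'
#' @param p_values vector of p-values.
#' @param ... passed to [plot()].
#' @return The [qq_data()] frame, invisibly.
#' @export
plot_qq <- function(p_values, ...) {
  d <- qq_data(p_values)
  plot(d$expected, d$observed,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(d)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(stats) / qchisq(0.5, 1)`: the median of the observed
#' 1-df chi-squared statistics relative to the null median (about 0.4549).
#' Values below 1 are returned as-is.
#'
#' @param chisq_1df_stats non-negative 1-df chi-squared statistics.
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(chisq_1df_stats) {
  stopifnot(length(chisq_1df_stats) >= 1L, all(chisq_1df_stats >= 0))
  stats::median(chisq_1df_stats) / stats::qchisq(0.5, df = 1)
}
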
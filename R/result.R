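#' Uniform test-result record
#'
#' All tests in this package return a `test_result`: the statistic, degrees
#' of freedom (possibly non-integer, possibly absent), p-value, and a
#' `defined` flag. An undefined result (e.g. the full-table chi-squared test
#' on a table with an empty category) carries `defined = FALSE`, `NA` fields
#' and a `note` giving the reason; replicate loops count these as 'NA'
#' outcomes rather than errors.
#'
#' @param test_name identifier, e.g. `"CHI-f"`, `"LR8"`, `"W"`.
#' @param statistic,df,p_value numeric scalars, `NA` when undefined.
#' @param note reason the result is undefined, `NA_character_` otherwise.
#' @return A list of class `test_result`.
#' @export
test_result <- function(test_name, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, note = NA_character_) {
  defined <- is.finite(p_value)
  if (defined && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(test_name = test_name,
                 statistic = as.numeric(statistic),
                 df = as.numeric(df),
                 p_value = as.numeric(p_value),
                 defined = defined,
                 note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("%s: statistic = %.4f, df = %g, p = %.6g\n",
                x$test_name, x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("%s: undefined (%s)\n", x$test_name, x$note))
  }
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(test = x$test_name, statistic = x$statistic, df = x$df,
             p_value = x$p_value, defined = x$defined,
             stringsAsFactors = FALSE)
}
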
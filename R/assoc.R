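#' Pearson chi-squared test on the full 2 x 9 genotype table
#'
#' The 'full-table' convention: the test is computed on all nine genotype
#' combinations with 8 degrees of freedom, and is undefined whenever any
#' category has a zero column total (the expected counts then contain
#' zeros). No continuity correction is applied.
#'
#' @param table a `pair_table`.
#' @return A `test_result` named `"CHI-f"`.
#' @export
chisq_full <- function(table) {
  stopifnot(inherits(table, "pair_table"), ncol(table$counts) == 9L)
  .chisq_table(table$counts, "CHI-f")
}

#' Pearson chi-squared test on the reduced genotype table
#'
#' The 'reduced-table' convention: categories with a zero total count are
#' removed before testing, giving a 2 x k' table and k' - 1 degrees of
#' freedom. Undefined when fewer than two categories remain or a row margin
#' is zero. Identical to [chisq_full()] when no category is empty.
#'
#' @param table a `pair_table`.
#' @return A `test_result` named `"CHI-r"`.
#' @export
chisq_reduced <- function(table) {
  stopifnot(inherits(table, "pair_table"))
  red <- observed_columns(table, "both_rows_zero")
  if (red$k < 2L)
    return(test_result("CHI-r", note = "fewer than 2 observed categories"))
  .chisq_table(red$table$counts, "CHI-r")
}

.chisq_table <- function(counts, name) {
  if (any(colSums(counts) == 0L) || any(rowSums(counts) == 0L))
    return(test_result(name, note = "empty row or column (zero expected count)"))
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result(name, statistic = unname(res$statistic),
              df = unname(res$parameter),
              p_value = stats::pchisq(unname(res$statistic),
                                      df = unname(res$parameter),
                                      lower.tail = FALSE))
}

#' Maximum-likelihood logistic fit
#'
#' Thin wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`) for binomial responses, returning the pieces the
#' likelihood-ratio tests need. Rank-deficient designs are handled by the
#' pivoted QR: aliased columns are dropped from the estimable basis and the
#' returned `rank` counts estimable parameters only. Fits hitting the
#' iteration cap (as under complete separation) return the capped
#' log-likelihood with `converged = FALSE`; the likelihood remains bounded
#' so LR statistics stay finite.
#'
#' @param design model matrix (include an intercept column explicitly).
#' @param response binary 0/1 vector (one row per individual) or a
#'   two-column matrix `cbind(cases, controls)` of grouped counts.
#' @param weights optional prior weights.
#' @param maxit IRLS iteration cap.
#' @return List with `loglik`, `coef` (NA for aliased terms), `vcov` (on the
#'   estimable basis), `rank`, `converged`, `fitted`.
#' @export
fit_logistic <- function(design, response, weights = NULL, maxit = 100L) {
  design <- as.matrix(design)
  if (is.matrix(response) && ncol(response) == 2L) {
    tot <- rowSums(response)
    y <- ifelse(tot > 0, response[, 1L] / tot, 0)
    w <- tot
  } else {
    if (!all(response %in% c(0, 1))) stop("response must be binary 0/1")
    y <- response
    w <- rep(1, length(y))
  }
  if (nrow(design) != length(y)) stop("design rows must match response length")
  if (!is.null(weights)) w <- w * weights
  fit <- suppressWarnings(
    stats::glm.fit(design, y, weights = w, family = stats::binomial(),
                   control = stats::glm.control(maxit = maxit)))
  mu <- fit$fitted.values
  keep <- w > 0 & mu > 0 & mu < 1
  ll <- sum((w * (y * log(mu) + (1 - y) * log(1 - mu)))[keep])
  p <- ncol(design)
  coef <- fit$coefficients          # glm.fit returns NA for aliased columns
  vc <- matrix(NA_real_, p, p)
  est <- !is.na(coef)
  if (any(est)) {
    Xe <- design[, est, drop = FALSE]
    wls <- w * mu * (1 - mu)
    xtwx <- crossprod(Xe * sqrt(wls))
    vc_e <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_,
                                                             sum(est), sum(est)))
    vc[est, est] <- vc_e
  }
  list(loglik = ll, coef = coef, vcov = vc, rank = fit$rank,
       converged = fit$converged, fitted = mu)
}

#' Specification of a logistic likelihood-ratio test
#'
#' `alt_terms` and `null_terms` name columns of the pair design:
#' `"x1"`, `"x2"`, `"x1:x2"` under allelic (dosage 0/1/2) coding, or the
#' genotypic indicator blocks `"g1"`, `"g2"`, `"g1:g2"` under genotypic
#' coding. The intercept is always included in both models.
#'
#' @param alt_terms,null_terms character vectors; `null_terms` must be a
#'   subset of `alt_terms`.
#' @param coding `"allelic_dosage"` or `"genotypic_indicators"`.
#' @param name test label.
#' @return A `logistic_spec` list.
#' @export
logistic_spec <- function(alt_terms, null_terms = character(0),
                          coding = c("allelic_dosage", "genotypic_indicators"),
                          name = "LR") {
  coding <- match.arg(coding)
  if (!all(null_terms %in% alt_terms))
    stop("null_terms must be a subset of alt_terms")
  structure(list(alt_terms = alt_terms, null_terms = null_terms,
                 coding = coding, name = name),
            class = "logistic_spec")
}

#' Built-in likelihood-ratio test specifications
#'
#' * `LR8`: saturated genotypic model (indicators for each genotype and
#'   their products) against intercept only; 8 df when all categories occur.
#' * `LR3`: allelic `a + b x1 + c x2 + i x1 x2` against intercept; 3 df.
#' * `LR1`: the same alternative against the main-effects model; 1 df test
#'   of pure (allelic) interaction.
#' * `LRI`: interaction-only `a + i x1 x2` against intercept; 1 df.
#'
#' @return A named list of `logistic_spec`s.
#' @export
lr_specs <- function() {
  list(
    LR8 = logistic_spec(c("g1", "g2", "g1:g2"), character(0),
                        "genotypic_indicators", name = "LR8"),
    LR3 = logistic_spec(c("x1", "x2", "x1:x2"), character(0),
                        "allelic_dosage", name = "LR3"),
    LR1 = logistic_spec(c("x1", "x2", "x1:x2"), c("x1", "x2"),
                        "allelic_dosage", name = "LR1"),
    LRI = logistic_spec("x1:x2", character(0),
                        "allelic_dosage", name = "LRI")
  )
}

# design columns for the 9 genotype categories (rows u slowest, as in the
# pair_table column order); terms selects named blocks
.pair_design <- function(terms, coding) {
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  cols <- list(`(Intercept)` = rep(1, 9L))
  if (coding == "allelic_dosage") {
    blocks <- list(`x1` = u, `x2` = v, `x1:x2` = u * v)
  } else {
    blocks <- list(
      `g1` = cbind(I1 = as.numeric(u == 1), I2 = as.numeric(u == 2)),
      `g2` = cbind(J1 = as.numeric(v == 1), J2 = as.numeric(v == 2)),
      `g1:g2` = cbind(I1J1 = (u == 1) * (v == 1), I1J2 = (u == 1) * (v == 2),
                      I2J1 = (u == 2) * (v == 1), I2J2 = (u == 2) * (v == 2)))
  }
  for (t in terms) cols[[t]] <- blocks[[t]]
  do.call(cbind, cols)
}

#' Likelihood-ratio logistic regression test on a pair table
#'
#' Fits nested logistic models to the grouped 2 x 9 counts (category-level
#' binomial responses give the same likelihood-ratio statistic and model
#' ranks as the individual-level fit) and compares them:
#' statistic `= 2 (l_alt - l_null)`, df = difference in estimable parameter
#' counts, p-value from the chi-squared upper tail. Structurally absent
#' genotype categories drop parameters via rank reduction, so the df adapts
#' to sparse tables; the result is undefined when 0 df remain or when the
#' phenotype is degenerate.
#'
#' @param table a `pair_table` (or anything accepted by [build_table()]
#'   already tabulated).
#' @param spec a `logistic_spec`, e.g. an element of [lr_specs()].
#' @return A `test_result`.
#' @examples
#' set.seed(1)
#' g1 <- rbinom(500, 2, 0.4); g2 <- rbinom(500, 2, 0.4)
#' tab <- build_table(g1, g2, rep(0:1, length.out = 500))
#' lr_test(tab, lr_specs()$LR3)
#' @export
lr_test <- function(table, spec) {
  stopifnot(inherits(table, "pair_table"), inherits(spec, "logistic_spec"))
  if (table$N1 == 0L || table$N0 == 0L)
    return(test_result(spec$name, note = "degenerate phenotype"))
  cnt <- table$counts
  present <- colSums(cnt) > 0L
  if (!any(present))
    return(test_result(spec$name, note = "empty table"))
  y <- cbind(cases = cnt[2L, present], controls = cnt[1L, present])
  Xa <- .pair_design(spec$alt_terms, spec$coding)[present, , drop = FALSE]
  Xn <- .pair_design(spec$null_terms, spec$coding)[present, , drop = FALSE]
  fa <- fit_logistic(Xa, y)
  fn <- fit_logistic(Xn, y)
  df <- fa$rank - fn$rank
  if (df <= 0L)
    return(test_result(spec$name, note = "0 df after rank reduction"))
  stat <- max(0, 2 * (fa$loglik - fn$loglik))
  res <- test_result(spec$name, statistic = stat, df = df,
                     p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
  res$converged <- fa$converged && fn$converged
  res
}

#' Run a battery of tests on one pair table
#'
#' @param table a `pair_table`.
#' @param tests character vector from `c("W", "CHI-f", "CHI-r", "LR8",
#'   "LR3", "LR1", "LRI")`.
#' @param hf passed to [w_test()] when `"W"` is requested.
#' @return Named list of `test_result`s.
#' @export
run_tests <- function(table, tests = c("W", "CHI-f", "CHI-r",
                                       "LR8", "LR3", "LR1", "LRI"),
                      hf = NULL) {
  specs <- lr_specs()
  out <- lapply(tests, function(t) {
    switch(t,
           "W" = w_test(table, hf),
           "CHI-f" = chisq_full(table),
           "CHI-r" = chisq_reduced(table),
           "LR8" = lr_test(table, specs$LR8),
           "LR3" = lr_test(table, specs$LR3),
           "LR1" = lr_test(table, specs$LR1),
           "LRI" = lr_test(table, specs$LRI),
           stop("unknown test: ", t))
  })
  names(out) <- tests
  out
}
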
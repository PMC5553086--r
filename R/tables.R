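#' Two-locus genotype-combination contingency tables
#'
#' A `pair_table` holds the 2 x 9 table of genotype-combination counts for a
#' pair of diallelic SNPs: row `"control"` holds the counts n0i, row `"case"`
#' the counts n1i, and the nine columns enumerate the SNP1 x SNP2 genotype
#' combinations in lexicographic order with the SNP1 genotype varying slowest
#' (dosage 0 = homozygous for allele 1). Column `3*u + v + 1` corresponds to
#' dosage `u` at SNP1 and dosage `v` at SNP2.
#'
#' @name pair_table
NULL

.pair_labels <- function() {
  g <- c("1/1", "1/2", "2/2")
  as.vector(t(outer(g, g, function(a, b) paste(a, b, sep = "x"))))
}

new_pair_table <- function(counts, labels = .pair_labels()) {
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(c("control", "case"), labels))
  structure(list(counts = counts,
                 N0 = sum(counts[1L, ]),
                 N1 = sum(counts[2L, ]),
                 column_labels = labels),
            class = "pair_table")
}

#' Build a 2 x 9 pair table from individual-level data
#'
#' Cross-tabulates two dosage vectors against a binary phenotype. Individuals
#' with a missing dosage at either SNP or a missing phenotype are dropped for
#' this pair only (complete-case per pair).
#'
#' @param geno1,geno2 integer dosage vectors in \{0, 1, 2\}, `NA` for missing.
#' @param phenotype binary vector, 0 = control, 1 = case, `NA` for missing.
#' @return A `pair_table` with `counts` (2 x 9 integer matrix, rows
#'   control/case), case and control totals `N1`, `N0`, and `column_labels`.
#' @examples
#' tab <- build_table(c(0, 0, 1), c(0, 1, 2), c(0, 1, 1))
#' tab$counts
#' @export
build_table <- function(geno1, geno2, phenotype) {
  n <- length(phenotype)
  if (length(geno1) != n || length(geno2) != n)
    stop("geno1, geno2 and phenotype must have equal length")
  ok_ph <- is.na(phenotype) | phenotype %in% c(0, 1)
  if (!all(ok_ph))
    stop("phenotype must be coded 0 (control) / 1 (case), NA for missing")
  bad_g <- function(g) !all(is.na(g) | g %in% c(0, 1, 2))
  if (bad_g(geno1) || bad_g(geno2))
    stop("genotypes must be dosages in {0, 1, 2}, NA for missing")
  keep <- !(is.na(geno1) | is.na(geno2) | is.na(phenotype))
  if (!any(keep)) stop("no complete records")
  idx <- 3L * as.integer(geno1[keep]) + as.integer(geno2[keep]) + 1L
  ph <- phenotype[keep]
  counts <- rbind(tabulate(idx[ph == 0], nbins = 9L),
                  tabulate(idx[ph == 1], nbins = 9L))
  new_pair_table(counts)
}

#' Construct a pair table directly from counts
#'
#' @param controls,cases length-9 non-negative integer vectors of category
#'   counts (column order as in [build_table()]).
#' @return A `pair_table`.
#' @export
pair_table <- function(cases, controls) {
  if (length(cases) != 9L || length(controls) != 9L)
    stop("cases and controls must each have 9 counts")
  if (any(cases < 0) || any(controls < 0) ||
      any(cases != round(cases)) || any(controls != round(controls)))
    stop("counts must be non-negative integers")
  new_pair_table(rbind(controls, cases))
}

#' @export
print.pair_table <- function(x, ...) {
  cat("2 x", ncol(x$counts), "genotype-pair table:",
      x$N1, "cases,", x$N0, "controls\n")
  print(x$counts)
  invisible(x)
}

#' Swap the roles of the two SNPs in a pair table
#'
#' Transposes the underlying 3 x 3 genotype grid, permuting column (u, v) to
#' (v, u). Every test in this package is invariant under this permutation.
#'
#' @param table a full 2 x 9 `pair_table`.
#' @return A `pair_table` with SNP1 and SNP2 exchanged.
#' @export
swap_snps <- function(table) {
  stopifnot(inherits(table, "pair_table"), ncol(table$counts) == 9L)
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  perm <- 3L * v + u + 1L
  new_pair_table(table$counts[, perm])
}

#' Reduce a pair table to its observed genotype categories
#'
#' Two reduction conventions are supported. `both_rows_zero` removes only
#' columns whose total count is zero (the convention of the reduced Pearson
#' chi-squared test). `any_row_zero` removes every column that is empty in
#' cases or in controls, and additionally columns where one row's count
#' equals that row's total (n = N), since the per-category standard error
#' involves 1/(N - n); this is the reduction required before computing
#' W-test cell statistics.
#'
#' @param table a `pair_table` (full or already reduced).
#' @param mode `"any_row_zero"` or `"both_rows_zero"`.
#' @return A list with `indices`, the retained column positions (relative to
#'   the input table, in original order), `table`, the reduced `pair_table`,
#'   and `k`, the number of retained columns. If no column survives, `k` is
#'   0, `table` is `NULL` and the result carries `empty_reduction = TRUE`.
#' @export
observed_columns <- function(table, mode = c("any_row_zero", "both_rows_zero")) {
  stopifnot(inherits(table, "pair_table"))
  mode <- match.arg(mode)
  cnt <- table$counts
  keep <- if (mode == "both_rows_zero") {
    colSums(cnt) > 0L
  } else {
    cnt[1L, ] > 0L & cnt[2L, ] > 0L &
      cnt[1L, ] < table$N0 & cnt[2L, ] < table$N1
  }
  idx <- unname(which(keep))
  if (length(idx) == 0L)
    return(list(indices = integer(0), table = NULL, k = 0L,
                empty_reduction = TRUE))
  list(indices = idx,
       table = new_pair_table(cnt[, idx, drop = FALSE],
                              labels = colnames(cnt)[idx]),
       k = length(idx),
       empty_reduction = FALSE)
}
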
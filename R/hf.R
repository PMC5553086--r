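#' Moment-matching estimator for scaled chi-squared parameters
#'
#' If `W = h * S` follows a chi-squared distribution with `f` degrees of
#' freedom, then `E(S) = f/h` and `Var(S) = 2f/h^2`, so
#' `h = 2 mean(S)/var(S)` and `f = 2 mean(S)^2/var(S)`.
#'
#' @param s numeric vector of pooled null statistics `S = sum(z^2)`
#'   (>= 2 values with positive variance).
#' @param k the category count these statistics share.
#' @return An `hf_params` with `source = "bootstrap"`, or `NULL` when the
#'   moments are not estimable.
#' @export
hf_moments <- function(s, k) {
  s <- s[is.finite(s)]
  if (length(s) < 2L) return(NULL)
  m <- mean(s); v <- stats::var(s)
  if (!is.finite(v) || v <= 0 || m <= 0) return(NULL)
  hf_params(h = 2 * m / v, f = 2 * m^2 / v, k = k, source = "bootstrap")
}

#' A per-k set of (h, f) parameters
#'
#' @param params list of `hf_params`, one per category count `k`.
#' @return An `hf_set`, indexable by `k` via [hf_lookup()].
#' @export
hf_set <- function(params) {
  ks <- vapply(params, `[[`, integer(1), "k")
  names(params) <- as.character(ks)
  structure(params, class = "hf_set")
}

#' @rdname hf_set
#' @param set an `hf_set`.
#' @param k category count to look up; falls back to [default_hf()] when
#'   the set has no entry for this `k`.
#' @export
hf_lookup <- function(set, k) {
  p <- set[[as.character(k)]]
  if (is.null(p)) default_hf(k) else p
}

#' @export
print.hf_set <- function(x, ...) {
  cat("W-test (h, f) parameter set:\n")
  for (p in x) print(p)
  invisible(x)
}

# S = sum z^2 and k for one pair of dosage columns under a null phenotype
.pair_S <- function(g1, g2, phenotype) {
  tab <- tryCatch(build_table(g1, g2, phenotype), error = function(e) NULL)
  if (is.null(tab)) return(c(NA_real_, NA_real_))
  cells <- cell_stats(tab)
  if (cells$k < 2L) return(c(NA_real_, NA_real_))
  c(sum(cells$z^2), cells$k)
}

#' Bootstrap estimation of the W-test (h, f) parameters
#'
#' Estimates the scale `h` and degrees of freedom `f` of the W-test's
#' reference distribution from a multi-SNP genotype panel, stratified by the
#' number of observed genotype categories `k`. Each of `B` bootstrap
#' replicates draws `min(n_individuals, N)` individuals and
#' `min(n_pairs, M(M-1)/2)` SNP pairs (both without replacement), assigns a
#' null phenotype by permuting the observed case/control labels (preserving
#' the case:control ratio), and computes `S = sum(z^2)` and `k` for every
#' sampled pair. The pooled null statistics are then moment-matched per `k`
#' via [hf_moments()]; values of `k` with insufficient pooled data fall back
#' to [default_hf()].
#'
#' @param genotypes N x M dosage matrix (0/1/2, `NA` missing).
#' @param n_cases number of cases among the N individuals (the permuted
#'   null phenotypes have this many 1s).
#' @param B bootstrap replicates (default 200).
#' @param n_pairs,n_individuals per-replicate caps (default 1000 each).
#' @param seed integer root seed; replicate b uses a derived stream so
#'   results are reproducible.
#' @return An `hf_set` with entries for each `k` in 2..9 that was observed.
#' @export
bootstrap_hf <- function(genotypes, n_cases, B = 200L,
                         n_pairs = 1000L, n_individuals = 1000L,
                         seed = 1L) {
  genotypes <- as.matrix(genotypes)
  N <- nrow(genotypes); M <- ncol(genotypes)
  if (M < 2L) stop("need at least 2 SNPs")
  if (N < 4L || n_cases < 2L || N - n_cases < 2L)
    stop("need at least 2 cases and 2 controls")
  n_pair_all <- M * (M - 1) / 2
  P_B <- min(n_pairs, n_pair_all)
  N_B <- min(n_individuals, N)
  pair_i <- rep(seq_len(M - 1L), times = (M - 1L):1L)
  pair_j <- unlist(lapply(seq_len(M - 1L), function(i) (i + 1L):M))
  S_all <- vector("list", B)
  k_all <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    rows <- if (N_B < N) sample.int(N, N_B) else seq_len(N)
    pairs <- if (P_B < n_pair_all) sample.int(n_pair_all, P_B)
             else seq_len(n_pair_all)
    pheno <- sample(rep(c(1L, 0L), c(round(n_cases * N_B / N),
                                     N_B - round(n_cases * N_B / N))))
    Sb <- numeric(length(pairs)); kb <- integer(length(pairs))
    for (p in seq_along(pairs)) {
      sk <- .pair_S(genotypes[rows, pair_i[pairs[p]]],
                    genotypes[rows, pair_j[pairs[p]]], pheno)
      Sb[p] <- sk[1L]; kb[p] <- as.integer(sk[2L])
    }
    S_all[[b]] <- Sb; k_all[[b]] <- kb
  }
  S <- unlist(S_all); kk <- unlist(k_all)
  ok <- is.finite(S)
  if (!any(ok)) stop("no SNP pair yielded a computable statistic")
  S <- S[ok]; kk <- kk[ok]
  params <- list()
  for (k in 2:9) {
    est <- hf_moments(S[kk == k], k)
    if (is.null(est)) est <- default_hf(k)
    params[[length(params) + 1L]] <- est
  }
  hf_set(params)
}

#' Write / read an (h, f) parameter set as plain text
#'
#' Serialises an `hf_set` to a tab-delimited file with columns
#' `k`, `h`, `f`, `source`, so panel-level estimates can be reused across
#' runs or supplied externally.
#'
#' @param set an `hf_set`.
#' @param path file path.
#' @export
write_hf <- function(set, path) {
  df <- data.frame(k = vapply(set, `[[`, integer(1), "k"),
                   h = vapply(set, `[[`, numeric(1), "h"),
                   f = vapply(set, `[[`, numeric(1), "f"),
                   source = vapply(set, `[[`, character(1), "source"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hf
#' @export
read_hf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  hf_set(lapply(seq_len(nrow(df)), function(i)
    hf_params(df$h[i], df$f[i], df$k[i], source = df$source[i])))
}
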
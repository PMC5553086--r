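#' Two-locus haplotype model
#'
#' Frequencies of the four haplotypes over two diallelic loci, ordered
#' (minor1-minor2, minor1-major2, major1-minor2, major1-major2). Derived
#' fields: the minor allele frequencies, the LD coefficient
#' `D = f(mm) f(MM) - f(mM) f(Mm)` and `r2 = D^2 / (p1 q1 p2 q2)`.
#'
#' @param freqs length-4 non-negative vector summing to 1.
#' @return A `haplotype_model` with `freqs`, `maf1`, `maf2`, `D`, `r2`.
#' @export
haplotype_model <- function(freqs) {
  if (length(freqs) != 4L || any(freqs < -1e-12) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 4 non-negative probabilities summing to 1")
  freqs <- pmax(freqs, 0); freqs <- freqs / sum(freqs)
  names(freqs) <- c("mm", "mM", "Mm", "MM")
  maf1 <- freqs[1L] + freqs[2L]
  maf2 <- freqs[1L] + freqs[3L]
  D <- freqs[1L] * freqs[4L] - freqs[2L] * freqs[3L]
  denom <- maf1 * (1 - maf1) * maf2 * (1 - maf2)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  structure(list(freqs = freqs, maf1 = unname(maf1), maf2 = unname(maf2),
                 D = unname(D), r2 = unname(r2)),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("haplotypes mm/mM/Mm/MM: %.4f %.4f %.4f %.4f  (MAF %.3f/%.3f, r2 = %.3f)\n",
              x$freqs[1], x$freqs[2], x$freqs[3], x$freqs[4],
              x$maf1, x$maf2, x$r2))
  invisible(x)
}

#' Solve haplotype frequencies for given MAFs and a target r-squared
#'
#' Inverts `r2 = D^2/(p1 q1 p2 q2)` with the positive-sign convention
#' (minor alleles positively associated): `D = sqrt(r2 * p1 q1 p2 q2)`, so
#' `f(mm) = maf1 * maf2 + D` etc. Errors when the implied `D` pushes any
#' haplotype frequency outside [0, 1], reporting the feasible r-squared
#' range for these MAFs.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @param target_r2 target squared correlation between the loci, in [0, 1).
#' @return A `haplotype_model` whose analytic `r2` equals `target_r2`.
#' @examples
#' solve_haplotypes(0.1, 0.1, 0.24)
#' @export
solve_haplotypes <- function(maf1, maf2, target_r2) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            target_r2 >= 0, target_r2 < 1)
  q1 <- 1 - maf1; q2 <- 1 - maf2
  D <- sqrt(target_r2 * maf1 * q1 * maf2 * q2)
  Dmax <- min(maf1 * q2, q1 * maf2)
  if (D > Dmax + 1e-12) {
    r2max <- Dmax^2 / (maf1 * q1 * maf2 * q2)
    stop(sprintf("target_r2 = %.3g infeasible for MAFs %.3g/%.3g; feasible range [0, %.4g]",
                 target_r2, maf1, maf2, r2max))
  }
  haplotype_model(c(maf1 * maf2 + D, maf1 * q2 - D, q1 * maf2 - D, q1 * q2 + D))
}

#' Population distribution over the 9 genotype combinations
#'
#' Each individual's two-locus genotype is the union of two independent
#' haplotype draws; returns the exact probabilities of the 9 dosage pairs
#' in `pair_table` column order (SNP1 dosage slowest, dosage = minor-allele
#' count).
#'
#' @param hap a `haplotype_model`.
#' @return Length-9 probability vector summing to 1.
#' @export
genotype_distribution <- function(hap) {
  stopifnot(inherits(hap, "haplotype_model"))
  f <- hap$freqs
  # haplotype h contributes (d1, d2) minor-allele dosages
  d1 <- c(1L, 1L, 0L, 0L); d2 <- c(1L, 0L, 1L, 0L)
  probs <- numeric(9L)
  for (a in 1:4) for (b in 1:4) {
    u <- d1[a] + d1[b]; v <- d2[a] + d2[b]
    idx <- 3L * u + v + 1L
    probs[idx] <- probs[idx] + f[a] * f[b]
  }
  probs
}

#' Penetrance models for two-locus disease risk
#'
#' Either a logit-linear model in the allele dosages,
#' `logit P(case | u, v) = alpha + beta u + gamma v + i u v`, or an
#' arbitrary 3 x 3 table of log odds of disease, one entry per genotype
#' combination (row = SNP1 dosage 0..2, column = SNP2 dosage 0..2). The
#' tabular form covers 'complex' effects not expressible on the allelic
#' scale.
#'
#' @param alpha,beta,gamma,interaction logit-linear coefficients.
#' @param log_odds 3 x 3 matrix of log odds for the tabular form.
#' @return A `penetrance_model`.
#' @export
penetrance_logit_linear <- function(alpha, beta = 0, gamma = 0,
                                    interaction = 0) {
  structure(list(form = "logit_linear",
                 alpha = alpha, beta = beta, gamma = gamma,
                 interaction = interaction),
            class = "penetrance_model")
}

#' @rdname penetrance_logit_linear
#' @export
penetrance_table <- function(log_odds) {
  log_odds <- as.matrix(log_odds)
  stopifnot(nrow(log_odds) == 3L, ncol(log_odds) == 3L,
            all(is.finite(log_odds)))
  structure(list(form = "table", log_odds = log_odds),
            class = "penetrance_model")
}

#' Penetrance over the 9 genotype categories
#'
#' @param pen a `penetrance_model`.
#' @return Length-9 vector of P(case | genotype) in `pair_table` column
#'   order.
#' @export
penetrance_vector <- function(pen) {
  stopifnot(inherits(pen, "penetrance_model"))
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  lo <- if (pen$form == "logit_linear") {
    pen$alpha + pen$beta * u + pen$gamma * v + pen$interaction * u * v
  } else {
    pen$log_odds[cbind(u + 1L, v + 1L)]
  }
  expit(lo)
}

#' Case and control genotype distributions under retrospective sampling
#'
#' Applies Bayes' rule to the population genotype distribution:
#' `P(g | case) = pen(g) P(g) / K` and
#' `P(g | control) = (1 - pen(g)) P(g) / (1 - K)` with `K` the population
#' prevalence. Also reports the implied minor allele frequencies among
#' cases and controls, used to calibrate scenarios to stated targets.
#'
#' @param genoprobs length-9 population genotype distribution.
#' @param pen a `penetrance_model` with penetrances strictly inside (0, 1).
#' @return List with `case`, `control` (length-9 distributions),
#'   `prevalence`, and `maf` (2 x 2 matrix: rows case/control, columns
#'   SNP1/SNP2).
#' @export
case_control_distributions <- function(genoprobs, pen) {
  stopifnot(length(genoprobs) == 9L, abs(sum(genoprobs) - 1) < 1e-8)
  pv <- penetrance_vector(pen)
  if (any(pv <= 0) || any(pv >= 1))
    stop("penetrances must lie strictly inside (0, 1)")
  K <- sum(pv * genoprobs)
  p_case <- pv * genoprobs / K
  p_ctrl <- (1 - pv) * genoprobs / (1 - K)
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  maf <- rbind(case = c(sum(u * p_case), sum(v * p_case)) / 2,
               control = c(sum(u * p_ctrl), sum(v * p_ctrl)) / 2)
  colnames(maf) <- c("snp1", "snp2")
  list(case = p_case, control = p_ctrl, prevalence = K, maf = maf)
}

#' Simulation scenario
#'
#' Bundles a haplotype model, a penetrance model and the sampling design of
#' one simulation study arm.
#'
#' @param haplotypes a `haplotype_model`.
#' @param penetrance a `penetrance_model`.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param replicates number of replicates the scenario calls for.
#' @param seed root seed.
#' @param label free-text description.
#' @return A `scenario`; the case/control genotype distributions are
#'   precomputed.
#' @export
scenario <- function(haplotypes, penetrance, n_cases = 500L,
                     n_controls = 500L, replicates = 1000L, seed = 1L,
                     label = "") {
  stopifnot(n_cases >= 1L, n_controls >= 1L, replicates >= 1L)
  dist <- case_control_distributions(genotype_distribution(haplotypes),
                                     penetrance)
  structure(list(haplotypes = haplotypes, penetrance = penetrance,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), label = label,
                 dist = dist),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d cases + %d controls, %d replicates\n",
              x$label, x$n_cases, x$n_controls, x$replicates))
  print(x$haplotypes)
  cat(sprintf("prevalence %.3f; case MAF %.4f/%.4f, control MAF %.4f/%.4f\n",
              x$dist$prevalence, x$dist$maf[1, 1], x$dist$maf[1, 2],
              x$dist$maf[2, 1], x$dist$maf[2, 2]))
  invisible(x)
}

# multinomial draw over the 9 categories expanded to dosage pairs
.draw_genotypes <- function(n, probs) {
  counts <- stats::rmultinom(1L, n, probs)[, 1L]
  idx <- rep.int(seq_len(9L), counts)
  if (n > 1L) idx <- sample(idx)        # shuffle individuals
  cbind(g1 = (idx - 1L) %/% 3L, g2 = (idx - 1L) %% 3L)
}

#' Draw one replicate of case/control genotype data
#'
#' Samples `n_cases` genotype pairs from the case distribution and
#' `n_controls` from the control distribution (retrospective ascertainment).
#' Reproducible: the replicate's RNG stream is derived from
#' `(scenario$seed, replicate_index)` only.
#'
#' @param scen a `scenario`.
#' @param replicate_index 1-based replicate number.
#' @return List with integer vectors `geno1`, `geno2` and `phenotype`
#'   (cases first, coded 1).
#' @export
sample_replicate <- function(scen, replicate_index = 1L) {
  stopifnot(inherits(scen, "scenario"))
  set.seed(derive_seed(scen$seed, replicate_index))
  gc <- .draw_genotypes(scen$n_cases, scen$dist$case)
  g0 <- .draw_genotypes(scen$n_controls, scen$dist$control)
  list(geno1 = c(gc[, 1L], g0[, 1L]),
       geno2 = c(gc[, 2L], g0[, 2L]),
       phenotype = rep(c(1L, 0L), c(scen$n_cases, scen$n_controls)))
}

#' Empirical r-squared between two dosage vectors
#'
#' Squared Pearson correlation of the two dosage vectors over complete
#' records.
#'
#' @param geno1,geno2 dosage vectors.
#' @return r-squared in [0, 1], or `NA` when either SNP is monomorphic in
#'   the sample.
#' @export
empirical_r2 <- function(geno1, geno2) {
  keep <- !(is.na(geno1) | is.na(geno2))
  g1 <- geno1[keep]; g2 <- geno2[keep]
  if (length(g1) < 2L) stop("need at least 2 complete records")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(NA_real_)
  stats::cor(g1, g2)^2
}

# analytic dosage r2 implied by a length-9 genotype distribution
.dist_r2 <- function(probs) {
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  mu_u <- sum(u * probs); mu_v <- sum(v * probs)
  var_u <- sum(u^2 * probs) - mu_u^2
  var_v <- sum(v^2 * probs) - mu_v^2
  cov_uv <- sum(u * v * probs) - mu_u * mu_v
  if (var_u <= 0 || var_v <= 0) return(NA_real_)
  cov_uv^2 / (var_u * var_v)
}
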
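#' Solve the baseline log-odds for a target prevalence
#'
#' Given the population genotype distribution and a penetrance-model
#' builder, finds the intercept `alpha` such that the population disease
#' prevalence equals `prevalence`. Only the conditional case/control
#' distributions matter for retrospective sampling, so `alpha` is a free
#' parameter pinned down by this convention.
#'
#' @param genoprobs length-9 population genotype distribution.
#' @param pen_fn function of one argument `alpha` returning a
#'   `penetrance_model`.
#' @param prevalence target population prevalence in (0, 1).
#' @return The calibrated `penetrance_model`.
#' @export
solve_alpha <- function(genoprobs, pen_fn, prevalence = 0.1) {
  stopifnot(prevalence > 0, prevalence < 1)
  f <- function(a) sum(penetrance_vector(pen_fn(a)) * genoprobs) - prevalence
  a <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
  pen_fn(a)
}

# Fixed-point calibration: choose population haplotype parameters so that
# the *control* MAFs and control dosage r2 hit the stated targets under the
# given effect model. With weak effects the fixed point is essentially the
# population value; with strong effects it corrects for case depletion.
.calibrate_controls <- function(target_maf1, target_maf2, target_r2,
                                pen_fn, prevalence = 0.1,
                                max_iter = 200L, tol = 1e-10) {
  m1 <- target_maf1; m2 <- target_maf2; r2 <- target_r2
  hap <- NULL; pen <- NULL
  for (it in seq_len(max_iter)) {
    hap <- solve_haplotypes(m1, m2, r2)
    gp <- genotype_distribution(hap)
    pen <- solve_alpha(gp, pen_fn, prevalence)
    ccd <- case_control_distributions(gp, pen)
    ctrl_maf <- ccd$maf["control", ]
    ctrl_r2 <- .dist_r2(ccd$control)
    if (max(abs(ctrl_maf - c(target_maf1, target_maf2)),
            abs(ctrl_r2 - target_r2)) < tol) break
    m1 <- min(0.5, m1 * target_maf1 / ctrl_maf[1L])
    m2 <- min(0.5, m2 * target_maf2 / ctrl_maf[2L])
    if (target_r2 > 0 && is.finite(ctrl_r2) && ctrl_r2 > 0) {
      q1 <- 1 - m1; q2 <- 1 - m2
      r2max <- min(m1 * q2, q1 * m2)^2 / (m1 * q1 * m2 * q2)
      r2 <- min(r2 * target_r2 / ctrl_r2, 0.999 * r2max)
    }
  }
  list(haplotypes = hap, penetrance = pen)
}

#' Null scenario: common MAF, no LD, no genotype effect
#'
#' Two independent SNPs with the given MAF and a constant penetrance, used
#' to measure type-I error (5000 replicates by convention).
#'
#' @param maf minor allele frequency of both SNPs.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param replicates replicate count.
#' @param seed root seed.
#' @param prevalence population prevalence fixing the baseline log-odds.
#' @return A `scenario`.
#' @export
scenario_null <- function(maf = 0.4, n_cases = 500L, n_controls = 500L,
                          replicates = 5000L, seed = 1L, prevalence = 0.1) {
  scenario(solve_haplotypes(maf, maf, 0),
           penetrance_logit_linear(alpha = logit(prevalence)),
           n_cases, n_controls, replicates, seed,
           label = sprintf("null, MAF %.2f, no LD", maf))
}

#' Main-effects-only scenario at common MAF
#'
#' Logit-linear model with equal main effects at both loci and no
#' interaction term: a positive control for association tests and a null
#' for tests of pure interaction.
#'
#' @inheritParams scenario_null
#' @param beta shared per-allele log-odds main effect.
#' @return A `scenario`.
#' @export
scenario_main_effects <- function(maf = 0.4, beta = 0.4, n_cases = 500L,
                                  n_controls = 500L, replicates = 1000L,
                                  seed = 1L, prevalence = 0.1) {
  hap <- solve_haplotypes(maf, maf, 0)
  pen <- solve_alpha(genotype_distribution(hap),
                     function(a) penetrance_logit_linear(a, beta, beta, 0),
                     prevalence)
  scenario(hap, pen, n_cases, n_controls, replicates, seed,
           label = sprintf("main effects only, MAF %.2f, beta %.2f", maf, beta))
}

#' Low-MAF scenario with LD calibrated to a control r-squared target
#'
#' Both SNPs at control MAF 0.1 with haplotype frequencies calibrated so
#' the analytic dosage r-squared *among controls* equals `target_r2`
#' (default 0.24), under a weak-to-moderate allelic effect model. The
#' default effect sizes were fixed once so that the combined case+control
#' dosage r-squared implied by the model comes out near 0.29, the companion
#' condition to the control-group 0.24.
#'
#' @inheritParams scenario_null
#' @param maf control-group minor allele frequency target.
#' @param target_r2 control-group dosage r-squared target.
#' @param beta,gamma,interaction allelic effect sizes.
#' @return A `scenario`.
#' @export
scenario_low_maf_ld <- function(maf = 0.1, target_r2 = 0.24,
                                beta = 0.1, gamma = 0.1,
                                interaction = 0.2,
                                n_cases = 500L, n_controls = 500L,
                                replicates = 1000L, seed = 1L,
                                prevalence = 0.1) {
  cal <- .calibrate_controls(maf, maf, target_r2,
                             function(a) penetrance_logit_linear(
                               a, beta, gamma, interaction),
                             prevalence)
  scenario(cal$haplotypes, cal$penetrance, n_cases, n_controls, replicates,
           seed,
           label = sprintf("low MAF %.2f, control r2 %.2f, allelic effects",
                           maf, target_r2))
}

# Stand-in 'complex' per-genotype log-odds offsets: chosen so that the
# pattern is not representable as alpha + beta*u + gamma*v + i*u*v (the
# allelic design), which is what makes the genotypic tests shine.
.complex_offsets <- function() {
  rbind(c(0, 0.0, 1.0),
        c(0, 1.0, 0.5),
        c(1, 0.5, 2.0))
}

#' Test whether a 3 x 3 log-odds table is allelic-representable
#'
#' Checks by least squares whether the table lies in the span of
#' `{1, u, v, uv}` over the nine dosage pairs.
#'
#' @param log_odds 3 x 3 matrix.
#' @param tol residual tolerance.
#' @return `TRUE` if an allelic model reproduces the table exactly.
#' @export
is_allelic_representable <- function(log_odds, tol = 1e-8) {
  u <- rep(0:2, each = 3L); v <- rep(0:2, times = 3L)
  X <- cbind(1, u, v, u * v)
  y <- as.vector(t(log_odds))          # row u slowest, matching (u, v) order
  res <- stats::lsfit(X, y, intercept = FALSE)$residuals
  max(abs(res)) < tol
}

#' Very-low-MAF strong-LD complex-effects scenario
#'
#' Both SNPs at control MAF 0.01 in strong LD (control dosage r-squared
#' 0.64) with disease risk given by a 3 x 3 per-genotype log-odds table
#' that is not representable on the allelic scale. The effect magnitude is
#' calibrated so the case-group MAF reaches `case_maf` (default 0.03,
#' i.e. a three-fold enrichment of the minor alleles among cases). The
#' log-odds pattern itself is a stand-in: the original study reports its
#' complex-effects table only graphically.
#'
#' @inheritParams scenario_null
#' @param maf control-group MAF target.
#' @param target_r2 control-group dosage r-squared target.
#' @param case_maf case-group MAF target fixing the effect magnitude.
#' @param offsets 3 x 3 matrix giving the shape of the per-genotype
#'   log-odds surface (scaled during calibration).
#' @return A `scenario`.
#' @export
scenario_rare_ld_complex <- function(maf = 0.01, target_r2 = 0.64,
                                     case_maf = 0.03,
                                     offsets = .complex_offsets(),
                                     n_cases = 500L, n_controls = 500L,
                                     replicates = 1000L, seed = 1L,
                                     prevalence = 0.1) {
  if (is_allelic_representable(offsets))
    stop("offsets are representable by the allelic model; supply a complex table")
  case_maf_at <- function(s) {
    cal <- .calibrate_controls(maf, maf, target_r2,
                               function(a) penetrance_table(a + s * offsets),
                               prevalence)
    gp <- genotype_distribution(cal$haplotypes)
    ccd <- case_control_distributions(gp, cal$penetrance)
    mean(ccd$maf["case", ])
  }
  s <- stats::uniroot(function(s) case_maf_at(s) - case_maf,
                      c(0.01, 12), tol = 1e-8)$root
  cal <- .calibrate_controls(maf, maf, target_r2,
                             function(a) penetrance_table(a + s * offsets),
                             prevalence)
  scenario(cal$haplotypes, cal$penetrance, n_cases, n_controls, replicates,
           seed,
           label = sprintf(
             "complex effects, control MAF %.2g, control r2 %.2f, case MAF %.2g",
             maf, target_r2, case_maf))
}

#' Common-MAF complex-effects scenario
#'
#' The complex per-genotype log-odds surface applied at common MAF with no
#' LD; a setting where genotypic tests outperform allelic ones.
#'
#' @inheritParams scenario_null
#' @param scale multiplier on the stand-in log-odds offsets.
#' @param offsets 3 x 3 log-odds offsets.
#' @return A `scenario`.
#' @export
scenario_complex_common <- function(maf = 0.4, scale = 0.4,
                                    offsets = .complex_offsets(),
                                    n_cases = 500L, n_controls = 500L,
                                    replicates = 1000L, seed = 1L,
                                    prevalence = 0.1) {
  hap <- solve_haplotypes(maf, maf, 0)
  pen <- solve_alpha(genotype_distribution(hap),
                     function(a) penetrance_table(a + scale * offsets),
                     prevalence)
  scenario(hap, pen, n_cases, n_controls, replicates, seed,
           label = sprintf("complex effects, MAF %.2f, scale %.2f", maf, scale))
}
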
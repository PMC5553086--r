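---
title: "Methods behind wpair: pairwise two-locus association testing"
author: "wpair maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind wpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpair)
```

## The testing problem

Given case/control genotypes at a pair of diallelic SNPs, the joint
genotype falls into one of $k \le 9$ combinations (3 genotypes at each
locus). Arranged as a $2 \times 9$ contingency table, with $n_{1i}$ cases
and $n_{0i}$ controls in category $i$ and totals $N_1$ and $N_0$, the
question of whether the joint genotype distribution differs between cases
and controls is a test of *association allowing for interaction*: the
alternative covers main effects, interaction effects, or both. A separate
and harder question is whether there is *statistical epistasis* — a
departure from additivity of the two marginal effects on the logit scale.
`wpair` implements one battery of both kinds of test and the simulation
machinery to compare them.

## The W-test

For each genotype category the package computes the normalized log odds
ratio between cases and controls,
$$
z_i = \frac{1}{SE_i}\,
  \log \frac{\hat p_{1i}/(1-\hat p_{1i})}{\hat p_{0i}/(1-\hat p_{0i})},
\qquad
SE_i = \sqrt{\tfrac1{n_{0i}} + \tfrac1{n_{1i}}
           + \tfrac1{N_0-n_{0i}} + \tfrac1{N_1-n_{1i}}},
$$
with $\hat p_{ji} = n_{ji}/N_j$, and combines them into the scaled
chi-squared statistic
$$
W = h \sum_{i=1}^{k} z_i^2 \;\sim\; \chi^2_f \quad \text{under } H_0 .
$$
The $k$ quantities $z_i$ are functions of two multinomial frequency
vectors and are therefore *not* independent; the scale $h$ and the
(possibly non-integer) degrees of freedom $f$ absorb that dependence.
Only categories observed in both rows enter the sum ($k$ shrinks
accordingly), and — going slightly beyond the "empty in cases and/or
controls" rule — categories in which one row's count equals its total are
also removed, because the $1/(N_j - n_{ji})$ terms of $SE_i$ are then
undefined. Frequencies and standard errors always use the full-sample
totals $N_j$, not the totals of the reduced table.

The combination form $W = h\sum z_i^2$ is our reconstruction: the original
description of the statistic is verbal, giving only the ingredients (the
$z_i$), the scaled-chi-squared reference and the default parameter values.
The default parameters $h = (k-1)/k$, $f = k-1$ are consistent with this
form — at $k$ categories a Pearson-type statistic carries $k-1$ df — and
the non-acceptance test suite confirms that under this reconstruction the
W-test is nearly equivalent to the saturated 8-df tests on common-variant
data, which is the behaviour the method is known for.

### Bootstrap estimation of $h$ and $f$

With genome-wide data, $(h, f)$ can be estimated from the data themselves.
`bootstrap_hf()` runs $B = 200$ replicates; each draws
$N_B = \min(1000, N)$ individuals and $P_B = \min(1000, P)$ SNP pairs
(both without replacement — the published procedure does not state the
replacement convention, and without-replacement subsampling avoids
duplicated records at these sizes), permutes the observed phenotype labels
(preserving the case:control ratio, i.e. a null in which genotype and
phenotype are independent), and records $S = \sum z_i^2$ and $k$ for every
sampled pair. Pooled across replicates and stratified by $k$, the moments
of $S$ identify the parameters: if $hS \sim \chi^2_f$ then
$\mathrm E(S) = f/h$ and $\mathrm{Var}(S) = 2f/h^2$, so
$$
\hat h = \frac{2\,\overline S}{\widehat{\mathrm{Var}}(S)}, \qquad
\hat f = \frac{2\,\overline S^2}{\widehat{\mathrm{Var}}(S)} .
$$
Moment matching is again our choice; the source description says only
"estimated using a bootstrapping approach". Strata with fewer than two
pooled values fall back to the default formulas. Because the $z_i$ are
negatively dependent through the multinomial constraint, the estimated
$f_k$ sits below $k$ (the independent-cell value); on common-MAF null
panels we observe $\hat f_9 \approx 8$, close to the default. Estimates
are reusable: `write_hf()`/`read_hf()` serialise the per-$k$ table, and
`scan_pairs(hf_mode = "bootstrap")` estimates once per panel and keeps
$(h, f)$ fixed across all test pairs, mirroring genomic-control practice.

Randomness is seeded from one root: replicate $b$ derives its own stream,
so results are reproducible and independent of evaluation order.

## Comparator tests

* **CHI-f** — Pearson's $X^2 = \sum (O-E)^2/E$ on the full $2\times9$
  table, 8 df. If any category total is zero the expected counts contain
  zeros and the test is *undefined* — this NA behaviour, not a failure
  mode, is one of the phenomena the benchmarking module quantifies.
* **CHI-r** — the same test after deleting zero-total categories:
  $k'-1$ df, defined whenever $k' \ge 2$. No continuity correction is
  applied anywhere, even when tables reduce to $2\times2$, keeping CHI-r a
  pure Pearson test at every $k'$.
* **LR8 / LR3 / LR1 / LRI** — likelihood-ratio tests between nested
  logistic regressions. LR8 uses the saturated genotypic coding (indicator
  variables for each single-locus genotype plus their products: one
  parameter per observed category) against an intercept-only null; its
  statistic equals the deviance $G^2$ of the contingency table. LR3, LR1
  and LRI use the allelic dosage coding $x_1, x_2 \in \{0,1,2\}$:
  LR3 tests $\alpha + \beta x_1 + \gamma x_2 + i x_1 x_2$ against
  $\alpha$ (3 df), LR1 tests the interaction term given the main effects
  (1 df, a test of pure allelic interaction), LRI tests
  $\alpha + i x_1 x_2$ against $\alpha$ (1 df). Prospective logistic
  modelling of retrospectively ascertained case/control data yields valid
  estimates of these odds-ratio parameters, which is why the intercept is
  the only distorted coefficient.

Fits run by iteratively reweighted least squares on the grouped
category-level binomial counts (identical likelihood-ratio statistics and
ranks to the individual-level fit, at a fraction of the cost). Missing
categories drop parameters through the pivoted-QR rank reduction, so the
df adapts to sparsity; a test whose df reaches zero is reported undefined.
Complete separation is handled by the iteration cap (100) and a
convergence flag rather than by removing categories — the LR statistic
remains finite even when a coefficient diverges. The IRLS convergence
criterion is a relative deviance change below $10^{-8}$.

## The two-locus simulator

Haplotype frequencies for loci with minor allele frequencies $p_1, p_2$
and LD coefficient $D$ are
$f(\text{mm}) = p_1 p_2 + D$, $f(\text{mM}) = p_1 q_2 - D$, etc., and
`solve_haplotypes()` inverts $r^2 = D^2/(p_1 q_1 p_2 q_2)$ with the
positive root, so the minor alleles co-occur — the conventional choice,
and the one that makes the rare-haplotype scenarios sparse in the way that
matters. Genotypes arise as the union of two independent haplotype draws;
`genotype_distribution()` expands this to the exact 9-category law.
Disease risk is either logit-linear in the dosages
($\alpha + \beta x_1 + \gamma x_2 + i x_1 x_2$) or an arbitrary
$3\times3$ log-odds table for "complex" surfaces that no allelic model
can represent (`is_allelic_representable()` verifies non-representability
by projecting onto the span of $\{1, u, v, uv\}$). Case/control sampling
is retrospective: $P(g \mid \text{case}) \propto \pi(g) P(g)$,
$P(g \mid \text{control}) \propto (1-\pi(g)) P(g)$.

The baseline $\alpha$ is solved per scenario so the population prevalence
is 0.1 — only the conditional distributions matter retrospectively, so
prevalence is a bookkeeping convention, recorded with the scenario.

### Calibration to stated study conditions

The benchmark scenarios state their LD and MAF conditions *among
controls*. Under a non-null model the control distribution is not the
population distribution, so `wpair` calibrates by fixed-point iteration:
population MAF and $r^2$ are adjusted until the analytic control-group
values hit the targets exactly (to $10^{-10}$). The shipped presets are:

* `scenario_null()` — MAF 0.4, no LD, constant penetrance; 5000
  replicates by convention for type-I error.
* `scenario_main_effects()` — MAF 0.4, $\beta=\gamma=0.4$, no
  interaction: a null for the pure-interaction tests only.
* `scenario_low_maf_ld()` — control MAF 0.1, control $r^2 = 0.24$. The
  allelic effect sizes ($\beta=\gamma=0.1$, $i=0.2$) are stand-ins — the
  source study reports its effect sizes only in figure annotations — fixed
  once so that the *emergent* combined case+control $r^2$ is about 0.29,
  the companion condition reported alongside the control-group 0.24.
* `scenario_rare_ld_complex()` — control MAF 0.01, control $r^2 = 0.64$,
  and a non-allelic $3\times3$ log-odds stand-in whose magnitude is
  calibrated so the case-group MAF is 0.03 (three-fold enrichment). The
  combined-sample $r^2$ then emerges at about 0.81 against a reported
  0.83, supporting the stand-in's adequacy. With $N = 1000$ and dosage-2
  probabilities near $10^{-4}$, some of the nine categories are
  essentially never all observed, which is what drives the full-table
  chi-squared NA accounting studied in the benchmark module.
* `scenario_complex_common()` — the same complex surface at MAF 0.4.

What the generator does *not* emulate: genotyping error, missingness,
population stratification, departure from Hardy-Weinberg proportions, and
more than two causal loci. Tests passing on these simulations therefore
validate the statistical machinery under clean ascertainment, not
robustness to the data-quality artefacts that dominate real GWAS
practice.

## Benchmarking conventions

`run_scenario()` simulates replicate data sets, runs every requested test
and aggregates at significance level $\alpha$ (default 0.05 — benchmark
figures in this literature rarely print their $\alpha$, so it is recorded
in every output header). Undefined results are counted under both
conventions: `power_defined` divides detections by the number of
replicates in which the test produced a result, `power_total` counts an
undefined result as a non-detection with all replicates in the
denominator. The distinction is the point: for sparse-data scenarios the
full-table chi-squared can be undefined in *every* replicate, making the
first convention 0/0 (reported `NA`, deliberately distinct from a true
power of zero) while the second reports 0. `qq_data()` pairs sorted
observed $-\log_{10} p$ with expected quantiles $(i - 0.5)/n$ computed on
the actually observed results, excluding undefined p-values with a logged
count, and `genomic_lambda()` is the median of 1-df statistics over the
null median $\chi^2_1$ quantile ($\approx 0.4549$), reported as-is also
when below 1.

## Numerical and design notes

* Chi-squared tails (including non-integer $f$) use the continuous gamma
  survival function via `pchisq`; no continuity correction.
* Table reduction is idempotent, and the W-test's `any_row_zero` rule
  removes a superset of the columns removed by the `both_rows_zero` rule
  used by CHI-r.
* Detection is declared at $p \le \alpha$.
* Missing data are handled complete-case per SNP pair — each pair drops
  only its own incomplete records, which is the natural convention for
  contingency construction.
* Dosages are oriented to the panel minor allele on load; at an exact
  50/50 frequency tie the alphabetically first allele is the reference.
* Simulation problem sizes used by the shipped test-suite checks: 5000
  null replicates for type-I error, 1000 replicates for the sparse-data
  accounting scenario, 50,000 pooled controls for LD verification, and
  $10^5$ per group for coefficient-recovery checks — sizes at which the
  binomial/Monte-Carlo error is small relative to the tolerances checked.

## Known limitations

* The W-test combination form and the moment estimator are
  reconstructions of a verbally described method; absolute agreement with
  the original software's statistic values on a given data set is not
  guaranteed (its genome-wide parameter tables are not reproduced here),
  though the default-parameter variant is fully determined and matches
  the described behaviour.
* The logistic fits use the grouped 9-category representation; covariate
  adjustment at the individual level is out of scope.
* Tables for three or more loci ($k = 3^L$) and single-SNP ($k=3$) scans
  are not implemented, though nothing in the data model precludes them.
* The pure-interaction tests from the wider epistasis literature (joint
  effects, adjusted Wu, adjusted fast epistasis, Wellek-Ziegler) are out
  of scope; LR1 is the representative interaction test here.
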
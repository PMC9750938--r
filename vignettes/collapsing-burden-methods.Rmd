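---
title: "Methods: rare-variant collapsing burden tests, MR, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant collapsing burden tests, MR, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exburden)
```

## The problem

Common-variant association studies explain part of the heritability of
complex diseases such as type 2 diabetes, but the contribution of rare
(minor allele frequency below 0.1%) protein-coding variation is best
measured by *collapsing* tests: all qualifying rare variants in a gene are
aggregated into a single 0/1 carrier indicator (the "dummy genotype") and
that indicator is tested against the trait. `exburden` implements such a
pipeline end to end — genotype-level quality control, functional masking,
carrier collapsing, a three-step generalised linear burden model with
inflation and heterogeneity diagnostics — together with the common-variant
follow-up analyses that typically accompany a new gene-disease signal: a
two-sample Mendelian randomization (MR) estimator suite and Bayes-factor
colocalization. Because real biobank genotypes are access-controlled, the
package also ships first-class synthetic-data generators that reproduce
the statistical structure each stage assumes; every calibration claim in
this vignette is recomputed by the test suite or the acceptance script.

## Genotype and variant quality control

Multi-allelic sites are split into biallelic records, trimmed to their
minimal representation and left-aligned against the reference context
(the same normalization `bcftools norm` performs). Genotype-level filters
then mirror standard exome-cohort practice:

* SNV calls with depth below 7 **and** genotype quality below 20, and
  indel calls with depth below 10 and genotype quality below 20, are set
  to missing. The rule is applied literally as a conjunction; because the
  disjunctive reading (either leg fails) is also common practice, the
  gate is switchable (`gate = "and"` default, `"or"` available).
* Heterozygous SNVs are tested for the expected 50% alternate-read
  contribution with an exact binomial test; calls with p &le; 10^-3^ are
  set to missing. Two-sided exact binomial p-values follow the
  minimum-likelihood convention (the sum of all outcome probabilities no
  larger than the observed one). At p~0~ = 0.5 this reduces *exactly* to
  `min(1, 2 * pbinom(min(k, n - k), n, 0.5))`, which is how the package
  computes it (vectorized); the test suite verifies agreement with direct
  pmf summation to 10^-12^ for every (k, n) with n &le; 200.
* After genotype filtering, per-variant missingness is recomputed and
  variants with missingness strictly above 50% are dropped. Allele counts
  (AC), called alleles (AN) and MAF are likewise recomputed from the
  surviving genotypes; recomputing frequency post-filter is an assumption
  (the source protocol states it only for missingness) and both behaviours
  are available by running the mask step on pre- or post-QC tables.

## Annotation, transcript prioritization, and masks

Each variant may be annotated against several transcripts. One record is
selected by the lexicographic priority *protein-coding &gt; MANE-select
&gt; canonical*; residual ties are broken by the lowest transcript
identifier so the choice is deterministic and order-independent (the
tie-break is a package convention — upstream tools do not document one).
Within the chosen record the most severe consequence is kept according to
a fixed severity ranking shipped with the package (in code as
`vep_severity_ranking` and as `extdata/severity_ranking.tsv`); unknown
terms raise an error rather than being silently ranked.

Stop-gained, frameshift, and splice acceptor/donor consequences form the
protein-truncating variant (PTV) class. The default mask set crosses five
functional classes — high-confidence (LOFTEE HC) PTVs, missense with
REVEL &ge; 0.5, missense with REVEL &ge; 0.7, synonymous (negative
control), and "damaging" (missense with CADD &ge; 25 or HC PTV) — with
two frequency strata, MAF &lt; 0.1% and singletons (AC = 1). Score
thresholds are inclusive, matching the printed "&ge;" conventions.
Variants missing a score their class requires are non-members and are
tallied for diagnostics. Hemizygous chrX dosage is not modelled by the
simulator and the collapsing rule treats any non-missing alternate
genotype as carrying.

## The three-step burden model

For each phenotype the package fits, once, a **null model**: an ordinary
least-squares regression of the trait (binary traits treated as
continuous at this stage) on the control covariates — age (standardized),
age squared, sex, ten genetic principal components, and sequencing batch
(3-level factor). For every gene-mask pair, the null-model residuals are
regressed on carrier status; this **preliminary** simple regression is
computed from sufficient statistics, so a 20,000-sample by 2,000-gene
scan takes seconds. Genes passing a lenient gate (preliminary p &lt;
10^-4^) get a **full** generalised linear model of the phenotype on
carrier status plus covariates with the appropriate family; for binary
traits the full fit reports OR = exp(beta) with exp(beta &plusmn; 1.96
SE) confidence bounds. For a 2x2 layout without covariates the full fit
reproduces the closed-form odds ratio and its Woolf standard error
`sqrt(1/a + 1/b + 1/c + 1/d)` to four significant figures, which the
tests assert.

A gene-mask pair is flagged *significant* only when its final p-value is
below the exome-wide threshold (default 6.9e-7; the effective-test
derivation behind that constant is not documented upstream, so it is a
configurable default) **and** it has at least 30 carriers (reporting
floor). Multiplicity across masks is handled by this single global
threshold, not FDR. Perfect separation and non-convergence are flagged on
the result (`converged = FALSE`), never fatal. Sample-exclusion re-runs
(e.g. dropping specific carriers for sensitivity analysis) are supported
via `screen_config(exclude_samples = ...)`, and effect heterogeneity
between two protein-domain partitions of a gene is tested with
`domain_partition_test()`, which applies the two-estimate Z test
`Z = (b1 - b2) / sqrt(se1^2 + se2^2)`.

### Inflation diagnostics and the binary-trait lattice

Genomic inflation is `lambda = median(qchisq(p, 1, lower.tail = FALSE)) /
0.4549364`. On the quantitative trait of the null simulator the screen is
calibrated to `lambda` within [0.98, 1.02] at 2,000 genes (and rejection
rate 0.04–0.06 at alpha = 0.05 with uniform p by Kolmogorov–Smirnov). For
a *rare binary* trait, however, the preliminary statistic is a function
of the integer number of case-carriers, so its null distribution lives on
a small lattice: the tail probabilities (rejection rates) remain
calibrated, but the *median* chi-square — and therefore lambda — can sit
several percent away from 1 at small carrier counts even for an exact
test. We verified this directly: the identical screen machinery yields
lambda = 0.999 on a gaussian trait and 1.05–1.14 on a 7.7%-prevalence
binary trait across carrier-count mixtures of 10–400. The acceptance
suite therefore asserts the lambda band on the quantitative trait and
asserts rejection rate and uniformity on the binary trait; users reading
QQ plots for rare binary traits should expect this granularity.

## The synthetic cohort generator

`simulate_cohort()` emulates, at reduced scale, a European-ancestry
biobank exome cohort with a 7.7% prevalent binary disease:

* **Site frequency spectrum.** MAFs are drawn log-uniformly (density
  proportional to 1/x, a heavy-tailed neutral-spectrum stand-in) between
  one allele copy and the 0.1% truncation; a configurable fraction of
  variants (default 0.5) are forced singletons (AC exactly 1). Genotypes
  follow Hardy–Weinberg sampling, and emitted AC/AN are recomputed from
  the realized genotypes, so allele accounting is exact by construction.
* **Read evidence.** Depth is negative-binomial (mean 40, size 8); GQ is
  truncated normal on [0, 99]; heterozygous alternate depths are
  binomial(DP, 0.5) with an error mode (rate 1%) drawing from an
  unbalanced binomial(DP, 0.12), and a low-quality mode (rate 1%) draws
  shallow depth with GQ &lt; 20 — so the QC filters have true positives.
  The real error process of biobank exome callers is not published; this
  noise model is a stand-in and is labelled as such.
* **Sparse call table.** All non-reference calls are explicit; homozygous
  reference calls are implicit and clean except for an explicit
  low-quality subset (rate 0.1%). This keeps a 15,000-sample by
  10,000-variant cohort in memory while preserving what QC needs; the
  VCF writer emits implicit hom-refs as `0/0:.:.:.` so the sparse table
  round-trips losslessly.
* **Phenotypes.** Disease is drawn from a logistic liability model,
  `logit P(y=1) = alpha + X b_cov + G b_gene`, with the intercept
  calibrated by root finding so the marginal prevalence matches the
  target (default 0.077). The liability link is logistic rather than
  probit because burden effects are reported as odds ratios; a carrier
  log-odds effect beta then yields a crude carrier OR of about exp(beta),
  which the tests confirm (median crude OR within 20% of 2.4 at
  n = 10^5, carrier frequency 10^-3, over 50 replicates). A quantitative
  trait with the same linear predictor and unit residual SD is emitted
  alongside. Principal-component surrogates are standard normal — no
  actual population structure or relatedness is simulated, so
  mixed-model correction is out of scope by design, and passing tests
  say nothing about confounding control on structured cohorts. No LD,
  haplotypes, or imputation are simulated either.

The end-to-end detection study plants 3 causal genes (ORs 5, 7, 10 on
the missense REVEL &ge; 0.7 mask) among 500 genes in a 15,000-sample
cohort with 20 variants per gene on average and singleton fraction 0.2 —
sizes chosen so the expected qualifying-carrier count per causal gene
(~130) gives high power at the exome-wide threshold while the whole
5-seed study stays in the minutes range. All 15 causal gene-seed pairs
are detected and no synonymous-mask test is ever flagged.

## Mendelian randomization suite

`harmonize()` joins exposure and outcome summary statistics on SNP id,
sign-flips outcome effects when allele labels are swapped, drops
palindromic (A/T, C/G) SNPs with effect-allele frequency in [0.42, 0.58]
(a common default window; the window is configurable), and orients every
instrument so the exposure-increasing allele is the effect allele.
Harmonizing an already-harmonized table is a no-op.

Estimators (all hand-authored and oracle-tested):

* **Wald ratio** per instrument: theta_j = b_y/b_x, SE = se_y/|b_x|.
* **IVW** — weighted regression through the origin with weights
  1/se_y^2; the fixed-effect SE is inflated by sqrt(Q/df) when Cochran's
  Q is overdispersed (multiplicative random effects; which variant the
  source analysis used is not documented, so `$se_fixed` is also
  reported). With one instrument IVW equals the Wald ratio exactly.
* **Egger** — weighted least squares with a free intercept; the
  intercept and its p-value test directional pleiotropy at p &lt; 0.05.
* **Weighted / penalised weighted median** — weighted median of Wald
  ratios (inverse-variance weights); the penalised variant multiplies
  weights by min(1, 20 q_j) with q_j the chi-square(1) upper-tail p of
  the instrument's deviation from IVW (penalty constant 20 from the
  originating publication; configurable). SEs come from a parametric
  bootstrap (1,000 draws, fixed seed, configurable).
* **Radial filtering** — iteratively removes instruments whose Q
  contribution has chi-square(1) upper-tail p below alpha/n (alpha
  default 0.05), to a fixed point; per-instrument contributions sum to
  Cochran's Q exactly.
* **Steiger filtering** — removes instruments explaining more variance
  in the outcome than the exposure, with r^2 = 2 EAF (1 - EAF) beta^2 on
  standardized traits; exact ties are retained, and instruments missing
  EAF or sample size pass through with a warning tally (the raw r^2
  comparison is used rather than a directionality-test p-value, the
  simpler of the two undocumented options).
* **Multivariable MR** — weighted least squares of outcome effects on
  the exposure-effect matrix without intercept, estimating the direct
  effect of the primary exposure adjusting for co-exposures (e.g. BMI
  and height). Identically-zero co-exposure columns are dropped (the fit
  then reduces exactly to IVW); rank-deficient exposure matrices raise
  an error naming the collinear columns.

`mr_all()` chains the filters and the four estimators and can rescale
estimates per SD of the exposure (e.g. 5.5 concentration units per SD).
Calibration facts the suite asserts: noiseless data are recovered to
machine precision; IVW 95% CI coverage is &ge; 18/20 seeds at theta =
0.1 with 200 instruments; Egger detects mean-0.05 directional pleiotropy
with power &ge; 0.8; the weighted median is closer to truth than IVW in
&ge; 80% of seeds when 30% of instruments are invalid; Steiger removes
every constructed reverse-causal instrument. LD-aware clumping and proxy
search require an LD reference panel and are out of scope; the
harmonizer operates on whatever pre-resolved instrument set it is given.

## Colocalization

For two summary-statistic tracks over a shared locus (the caller chooses
the window, e.g. &plusmn;500 kb around a gene), each SNP gets a Wakefield
log approximate Bayes factor, `0.5 log(se^2/(se^2+W^2)) + 0.5 z^2
W^2/(se^2+W^2)`, with prior effect SD W = 0.15 for quantitative traits
(0.2 conventional for case-control). Hypothesis masses for H0 (no
association), H1/H2 (one trait only), H3 (two distinct causal variants),
and H4 (one shared causal variant) are accumulated in log space
(log-sum-exp; the H3 sum over ordered pairs uses the factorization
sum_i sum_{j != i} = (sum_i)(sum_j) - sum_i(ii), computed with a stable
log-difference), so loci with |z| = 50 remain finite. Priors default to
p1 = p2 = 10^-4, p12 = 10^-5 (the conventional defaults; configurable).
Posteriors sum to 1 within 10^-12, are invariant to SNP order, and PP4
is monotone in p12. One causal variant per trait is assumed — no
multi-signal conditioning or fine-mapping — which is precisely the
regime where real loci with multiple independent signals can favour H3.

## Numerical and engineering choices

* Coordinates are 1-based inclusive (VCF convention) everywhere; TSVs
  are UTF-8, tab-delimited, `.` for missing.
* Degenerate inputs have defined behaviour: zero carriers yields a skip
  record, an all-carrier gene is a no-contrast error, empty masks are
  logged and skipped, zero total reads is an error for the
  allele-balance test, and missingness exactly 50% is retained (the drop
  rule is strict).
* `run_pipeline()` is deterministic given its seed; its JSON manifest
  records the seed, thresholds, and variant counts into and out of every
  filter (counts are conserved: in = kept + dropped).
* Validation problem sizes: 2,000 genes by 20,000 samples for null
  calibration, 10 x 2,000 tests for pooled lambda, 50 replicates at
  n = 10^5 for effect recovery, 5 seeds of the 500-gene screen, 20–50
  seeds per MR property, 10 seeds per colocalization scenario. These
  were chosen as the smallest studies that make the corresponding
  statistical claims sharp.

## Known limitations

Relatedness, population structure, LD, imputation, and chrX dosage are
not simulated, so the pipeline's calibration on these data does not
demonstrate robustness to confounding by structure (the motivation for
mixed models in real cohorts). The genotype noise model is a stand-in
for an unpublished error process. The binary-trait lattice effect on
lambda described above is a property of exact rare-carrier statistics,
not removable by implementation. Colocalization assumes a single causal
variant per trait per locus.
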
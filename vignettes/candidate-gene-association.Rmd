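---
title: "Candidate-gene SNP association for a binary tolerance phenotype: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene SNP association for a binary tolerance phenotype: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salsnp)
```

This vignette is the package's own account of the statistical methods it
implements, the conventions it adopts where the workflow leaves choices
open, and what its tests do and do not establish. The setting is a
candidate-gene marker-validation study: a handful of biallelic SNPs in an
osmoregulation gene, genotyped by direct Sanger sequencing in two
phenotype cohorts (low-salinity tolerant and intolerant, around 50
individuals each), with growth traits and qPCR expression measured on the
tolerant side.

## Genotype calling and filtering

Direct-sequencing heterozygote detection works on the ratio of the
secondary to the primary chromatogram peak at the SNP position.
`call_genotype_from_peaks()` calls a heterozygote when the ratio is at
least `het_ratio` (default 0.30) and a homozygote for the primary base
when it is below `noise_ratio` (default 0.20). The band in between is
genuinely undefined by the calling rule; we mark such calls **missing**
rather than forcing either interpretation, because in practice equivocal
traces are re-sequenced or cross-checked rather than guessed. Calling is
therefore monotone in the secondary peak height (hom → missing → het),
which the tests assert over a sweep of ratios.

The MAF filter (`filter_loci_by_maf()`, default 5%) compares the **minor
allele count** against `threshold × 2n` rather than comparing floating
frequencies, so the boundary case of 4 minor alleles among 64 passes
exactly; 0.05 has no finite binary representation and a naive `>=` on
frequencies can drop a boundary locus. Loci are strictly biallelic: a
third allele at ingestion is an error naming the sample and locus, never
a silent recode.

## Per-locus case–control statistics

Association uses the carrier (dominant) coding — heterozygotes and
alternate homozygotes pooled against homozygous wild type — which matches
how "mutant genotype frequency" is compared in this kind of study; a
per-genotype 3-row table is available via
`carrier_contingency(..., coding = "genotype")`.

On the 2×2 table (n1 = tolerant carriers, n2 = tolerant wild types,
n3/n4 the same in the intolerant group):

* **Odds ratio** `n1·n4 / (n2·n3)`, undefined (reported `"-"`) when either
  product is zero.
* **Confidence interval**: the Woolf log-normal interval
  `exp(ln OR ± z·sqrt(1/n1 + 1/n2 + 1/n3 + 1/n4))` with z = 1.96. The
  interval method is rarely stated in application papers; the Woolf form
  is adopted here because it reproduces published intervals of this
  workflow to the printed precision.
* **Chi-square**: the uncorrected Pearson statistic. Yates continuity
  correction is deliberately not applied — the corrected statistic does
  not reproduce the published values this pipeline targets, and for
  expected-count tables the correction has no clear justification.
* **Fisher exact test**: two-sided by hypergeometric enumeration, summing
  all tables at the observed margins whose probability does not exceed
  the observed table's (relative tie slack 1e-12). The test requires
  integer cells; fractional EM expected counts must pass through
  `round_half_even_2x2()` first and the resulting p is labelled
  approximate — an exact test on fractional pseudo-counts is not a
  defined object, and half-to-even rounding at least keeps totals nearly
  unbiased.
* **Logistic effect size**: `logistic_single_locus()` fits
  tolerant ~ carrier by IRLS. With a single binary predictor the ML slope
  equals `ln(OR)` and its standard error the Woolf SE — an algebraic
  identity the tests assert to 1e-6, so the effect-size display can never
  drift from the contingency statistics. A zero cell is reported as
  `separation` with undefined estimates rather than a huge finite number.

No multiple-testing correction is applied; with four pre-specified
candidate loci the raw p-values are reported as such, and this is stated
in the output rather than silently assumed.

## Diversity summaries

For allele frequencies `p_i` over typed genotypes in one group:
`He = 1 − Σp²` (plug-in gene diversity, no 2n/(2n−1) small-sample
correction), `Ne = 1/Σp²`, and
`PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²`. The uncorrected plug-in form is used
because it preserves the exact identity `He = 1 − 1/Ne`, which published
tables of this workflow satisfy row by row; the bias-corrected form does
not. `Ho` is simply the heterozygote fraction. A monomorphic locus gives
(0, 0, 1, 0).

## EM haplotype inference

Unphased multi-locus genotypes are phased statistically under
Hardy–Weinberg random pairing. An individual heterozygous at *h* loci has
`max(1, 2^(h−1))` unordered compatible haplotype pairs
(`enumerate_phase_configurations()`); the E-step weights each pair by
`f(h1)·f(h2)·(2 − [h1 = h2])` normalized within the individual, and the
M-step divides expected haplotype copy counts by `2n`. Numerical choices:

* **Initialization** is the deterministic linkage-equilibrium start
  (products of single-locus allele frequencies). Three seeded Dirichlet
  random restarts (default `seed = 1`) guard against flat or symmetric
  starts; the best final log-likelihood wins. With four loci and real
  data the restarts virtually always agree with the LE start.
* **Convergence** at a maximum absolute frequency change below 1e-8 —
  much tighter than the two decimals at which expected counts are
  reported, so reported values are insensitive to the stopping rule.
* **Missing data**: individuals with any missing call at the requested
  loci are excluded (and counted in `n_excluded`); integrating over
  missing genotypes is out of scope.
* Frequencies driven below 1e-10 are floored to zero and renormalized:
  they are true zeros of the MLE reached asymptotically, and flooring
  keeps downstream "zero count ⇒ undefined statistic" conventions exact.
* The log-likelihood is monotonically nondecreasing across iterations —
  asserted on every dataset the tests touch, as it is the sharpest cheap
  invariant of a correct EM.

## The haplotype association table

`build_haplotype_table()` forms, for each haplotype, the 2×2 table "this
haplotype vs all others" on the EM expected counts, with group totals
summing **only haplotypes at or above `rare_threshold` (default 0.03)
relative frequency in at least one group**. Rare haplotypes keep their
counts in the output but get `"-"` statistics. This exclusion convention
is the only way the published tables of this workflow are arithmetically
self-consistent; the exact threshold is not recoverable from such papers
(any value between the largest excluded and smallest included frequency
reproduces them), and 0.03 — the common default of haplotype-analysis
servers — is adopted and exposed as an argument. Chi-square and OR are
computed on the fractional counts directly; the Fisher column uses the
half-even-rounded table and is flagged approximate.

## The genotype-frequency classifier

`fit_frequency_model()` stores, per group and locus, the relative
frequency of each genotype among typed training samples.
`classify()` multiplies the sample's genotype frequencies across loci per
group and predicts the group with the larger product — a naive-Bayes-style
rule without priors, exactly as this workflow defines it.

* **Smoothing**: a genotype unseen in one group would annihilate that
  group's product. The default pseudo-frequency of 0.005 (about half of
  1/(2·50) at the typical group size) replaces exact zeros at scoring
  time; `smoothing = 0` restores the strict literal rule. The default is
  small enough never to flip a comparison between two nonzero products.
* **Ties** (equal scores) are classified intolerant — the conservative
  direction for a tolerance-selection marker, and switchable.
* **Evaluation** is resubstitution by default, which is what the
  validation accuracy `R = N_correct/N_all × 100%` describes in this
  workflow; a leave-one-out mode is provided because resubstitution
  optimism is a known hazard at n = 100 with 3^4 possible genotype
  profiles. On well-separated synthetic data the two agree within a few
  points, which the tests check as a regression guard, not a theorem.
* Samples with a missing call at any model locus are excluded from
  scoring and accuracy and reported in `n_excluded`, rather than imputed.

## Growth PCA and growth groups

`correlation_pca()` standardizes the three traits and eigendecomposes the
correlation matrix, reporting loadings as `eigenvector·sqrt(eigenvalue)`
(the trait–component correlations). Correlation rather than covariance
PCA is the right choice for traits on incommensurate scales (mm vs g),
and it is the parameterization under which published loading tables of
this workflow are internally consistent (eigenvalues summing to the trait
count). Eigenvector signs are fixed so each component's loading sum is
nonnegative; for morphometrics this orients PC1 as an overall size axis,
and `assign_growth_groups()` additionally guarantees a larger body weight
gives a larger PC1 score before taking the top and bottom `n_per_group`
(default 25) samples as fast- and slow-growing groups. Boundary ties are
broken by input order, deterministically.

`growth_group_genotype_table()` reports per-locus carrier counts in the
two growth groups with frequencies defined as each group's carriers over
the **total carriers across both groups**. Published tables of this
workflow are inconsistent about this denominator between rows; the
shared-total convention reproduces their unambiguous rows exactly and is
applied uniformly rather than guessed per row.

## Relative expression

`relative_expression()` averages technical replicates on the Ct scale,
takes `ΔCt = Ct_target − Ct_reference`, references against the mean ΔCt
of the calibrator genotype (default the homozygous wild type), and
reports `2^−ΔΔCt`. Averaging replicates before ΔCt is the standard
convention; amplification-efficiency correction is out of scope.
`anova_posthoc()` runs one-way ANOVA with Tukey HSD and a compact-letter
display (insert-and-absorb). Tukey is the default because it is what
figure captions of this workflow actually apply, even when the methods
text names Duncan's test; Duncan's multiple range test (studentized range
at protection level `1 − (1−α)^(p−1)`) is available via
`method = "duncan"`.

## The synthetic-data generator

`simulate_population()` draws two whole haplotypes per individual from
its group's haplotype distribution — the defaults are the renormalized
published group frequencies of the four-SNP panel — so the linkage
disequilibrium between loci is implicit in the generating model rather
than bolted on. Missing calls are injected at 2% by default, matching
the near-complete typing that published allele totals imply. Growth
traits follow a one-factor model (common size factor plus trait noise,
pairwise correlation 0.95, defaults 20 mm / 28 mm / 5 g with SDs 3 / 4 /
1.2 — juvenile-scale values) with carriers shifted up 0.8 SD on the size
factor; expression records shift target Ct down 0.5 cycles per
heterozygote and 1.0 per alternate homozygote (expected folds 1.41 and
2.0) with 0.1-cycle technical noise; peak tables place heterozygotes at
ratios 0.35–0.9 and homozygotes at 0–0.15, with an optional ambiguous
fraction in 0.20–0.30.

What the generator does **not** emulate: the salinity-challenge survival
process itself, family or population structure, genotyping error other
than missingness, allele-specific peak-height biases, reference-gene
instability, or any trait–genotype architecture beyond the single carrier
shift. Passing tests on this synthetic structure therefore show the
pipeline's arithmetic and inference are correct under the stated model —
not that the model captures every feature of real sequencing data.

## Problem sizes and test design

The test suite exercises EM recovery and the classifier on cohorts of 500
individuals per group (1000 gametes), where multinomial sampling gives
standard errors around 0.016 for the most common haplotype; smaller
checks use 30–250 individuals. At these sizes a ±0.03 recovery band on
the leading haplotype corresponds to roughly 1.9 standard errors before
accounting for the phase information lost in unphased genotypes, so
occasional excursions beyond it are expected behaviour of a correct
estimator, not a defect. The Fisher implementation is checked against an
independent binomial-coefficient enumeration over **all** 2×2 tables with
total at most 40, and the logistic/Woolf identities over random tables.

## Known limitations

* Resubstitution accuracy overstates out-of-sample performance; use
  `mode = "loo"` for an honest estimate on small panels.
* Fisher p-values on rounded EM expected counts are approximate by
  construction.
* The EM excludes partially typed individuals instead of integrating over
  them, slightly reducing efficiency at high missingness.
* Diversity estimators are plug-in (no small-sample correction) by
  design, to preserve the `He = 1 − 1/Ne` identity.
* The classifier has no regularization or model selection; it is the
  literal genotype-frequency-product rule, with smoothing as the only
  guard.
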
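---
title: "Methods: summary-based methylome-wide association with SMR and HEIDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-based methylome-wide association with SMR and HEIDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrmwas)
```

## The question the package answers

Case-control GWAS find SNPs associated with disease; mQTL studies find SNPs
associated with CpG methylation. When the same SNP does both, the association
may be *pleiotropic* — one causal variant shifting methylation, which in turn
(or in parallel) shifts disease risk — or it may be *linkage*: two distinct
causal variants in LD, one per trait. This package implements the
summary-statistics-only workflow that separates the two: the SMR ratio test
for the methylation-disease effect at each probe's top cis-mQTL instrument,
and the HEIDI heterogeneity filter over the instrument's LD neighbourhood.
Around that core it provides allele harmonization and fixed-effects
meta-analysis of cohort GWAS, Wald chi-square scans for stratum-specific
effects, cross-tissue concordance, probe annotation, catalog-based locus
classification, and competitive pathway enrichment.

## Model and assumptions

Writing $z = b/se$ for any summary effect, the SMR estimate at the top
instrument is $\hat b_{SMR} = b_{by}/b_{zx}$ with test statistic

$$T_{SMR} = \frac{z_{by}^2\, z_{zx}^2}{z_{by}^2 + z_{zx}^2}, \qquad
P_{SMR} = \Pr(\chi^2_1 > T_{SMR}).$$

$T_{SMR} \le \min(z_{by}^2, z_{zx}^2)$, so $P_{SMR}$ is never smaller than
either component p-value; the package enforces this identity and defines
$SE_{SMR}$ by first-order error propagation,
$SE_{SMR}^2 = (se_{by}^2 + \hat b_{SMR}^2 se_{zx}^2)/b_{zx}^2$, which makes
$(b_{SMR}/SE_{SMR})^2 = T_{SMR}$ hold exactly (and stays finite when
$b_{by} = 0$). Published result tables sometimes print a $P_{SMR}$ smaller
than the top SNP's $P_{GWAS}$, which contradicts this bound; the package
treats the $(b_{SMR}, SE_{SMR}, P_{SMR})$ triple as the internally consistent
object and checks printed tables through it.

Assumptions: the GWAS and mQTL studies are independent samples from the same
ancestry (their errors are uncorrelated across studies but correlate as the
allelic correlation $r$ within a study); effects are additive per allele; the
ratio is informative only where $b_{zx}$ is well away from zero, which is why
instruments require $P_{mQTL} < 5\times 10^{-8}$.

### HEIDI

For each retained neighbour SNP $i$, $d_i = \hat b_{SMR}(i) - \hat
b_{SMR}(\mathrm{top})$. Under a single shared causal variant all $d_i$ have
mean zero; their covariance follows from the same first-order propagation,
with SNP pairs coupled through the panel-estimated dosage correlation
$r_{ij}$ within each study. The statistic $Q = \sum_i z_{d_i}^2$ is then a
weighted sum of 1-df chi-squares with weights equal to the eigenvalues of the
correlation matrix of the standardized deviations. Candidate SNPs must have
$P_{mQTL} < 1.6\times 10^{-3}$ (so each ratio is itself estimable) and
$r^2$ to the top SNP in $[0.05, 0.9]$ — enough LD to share the signal, not so
much that the deviation is pure noise; pairs above $r^2 = 0.9$ are greedily
pruned keeping the stronger mQTL $|z|$. All four thresholds are arguments of
`heidi_test()`. These are the conventional defaults of the method; the source
study reports using them unchanged.

Counting convention: `n_heidi` includes the top SNP and is capped at 20 (the
cap in published result tables); at least 3 SNPs including the top are
required, otherwise `p_heidi` is `NA` and the probe is flagged
`heidi_not_evaluable` rather than silently passed. Whether unevaluable probes
count as retained is a switch (`keep_unevaluable`, default off).

### Numerical evaluation of the weighted tail

`wchisq_tail()` inverts the characteristic function by Imhof's integral with
`stats::integrate` (1000 subdivisions, relative tolerance $10^{-9}$), clamped
to $[0,1]$; if quadrature fails it falls back to Satterthwaite moment
matching. The tests validate the quadrature against a brute-force Monte-Carlo
oracle (200,000 draws of $\sum_k \lambda_k \chi^2_{1,k}$) on random weight
vectors, requiring agreement within three Monte-Carlo standard errors.

### Meta-analysis and harmonization

Cohorts are combined by fixed-effects inverse variance: weights $1/se^2$,
pooled SE $(\sum w)^{-1/2}$. No random-effects variant is provided, matching
the source analysis. Before pooling (and before the scan), every table is
harmonized to a reference allele coding: swapped alleles flip the sign of $b$
and replace $freq$ by $1-freq$; strand-palindromic SNPs (A/T, C/G) with
frequency in $[0.4, 0.6]$ are dropped as unresolvable — a conventional
safeguard the source leaves unstated. A SNP missing from some cohorts is
pooled over the cohorts that report it, with the count recorded.

### Stratified and cross-tissue comparisons

`wald_chisq_diff()` computes $\chi^2 = (b_1-b_2)^2/(se_1^2+se_2^2)$, df 1.
The group scan defines candidates as probes passing both filters in
*exactly one* stratum (exclusive-or): probes significant in both strata were
handled separately in the source analysis, so "detected in either group" is
read exclusively. The family size $m$ is the candidate count and the flag
threshold $0.05/m$. The other stratum's estimate is required even when
non-significant; candidates absent from the other stratum's tested set are
skipped and logged, never imputed. For cross-tissue concordance the family
size defaults to the shared-probe count (the source leaves this denominator
unstated); each analysis keeps its own top instrument, and the per-analysis
estimates are compared as reported.

### Annotation and enrichment

Probes inside a gene body or within 1,500 bp of a TSS are assigned to that
gene, closest TSS winning among multiple hits; intergenic probes go to the
nearest gene. Nearest is measured probe-to-TSS by default (the source states
no metric; a `metric = "boundary"` switch measures to the closest gene edge).
Locus classification against a catalog uses strict printed boundaries:
G if any entry within ±1 Mb has $p < 5\times 10^{-8}$, else S if any has
$5\times 10^{-8} \le p < 5\times 10^{-6}$, else N — so $p$ exactly
$5\times 10^{-8}$ is S and exactly $5\times 10^{-6}$ is N.

The gene score for enrichment is $\max(-\log_{10} P_{SMR})$ over the gene's
probes — the simplest defensible competitive score; the external tool the
source used applies a k-th-best/monotonization scheme that is not
reproducible from its description, so the two are not equivalent. The set
statistic is $z = (\bar s_{set} - \bar s)/(\sigma_{pop}/\sqrt{count})$ with
the *population* SD, since a set is compared against the full scored-gene
population; when all scores are equal the set carries no information and
$z = 0, p = 0.5$. Benjamini–Hochberg q-values come from `stats::p.adjust`.
The FDR-level rule marks a level $\ell$ admissible when
$\ell \times \#\{q \le \ell\} < 1$ (fewer than one expected false positive)
and chooses the largest admissible level; the full admissible set is
reported, because the published per-plan choices are not always the maximal
admissible ones and the rule alone does not determine them.

## The synthetic-data generator

Every stage is testable without external downloads against simulated studies
with known truth. The LD model is a latent-Gaussian AR(1): each haplotype is
an autoregressive Gaussian vector with adjacent correlation `ld_rho`,
thresholded at the quantile of the SNP's minor-allele frequency; dosages are
the sum of two independent haplotypes, giving Hardy-Weinberg genotypes and a
one-parameter LD decay with closed-form latent structure. MAFs are drawn
independently and uniformly from `maf_range` (default $[0.05, 0.45]$).
Because $r^2$ between SNPs is bounded by MAF similarity, thresholding plus
MAF heterogeneity attenuates the dosage-scale correlation well below the
latent `ld_rho`: direct Monte-Carlo evaluation of this model puts the mean
adjacent-pair dosage correlation near 0.60 at `ld_rho = 0.9`, and the tests
freeze that oracle-derived band.

Scenarios: under *pleiotropy* one causal SNP drives methylation
($y = \beta_{zx} g + \varepsilon$, $\varepsilon \sim N(0,1)$) and disease
risk follows a logistic model in the methylation value ($b_{xy}$ log-odds per
methylation unit); under *linkage* a second SNP `linkage_gap` positions away
affects disease directly; under the *null* disease is independent of
genotype; *group heterogeneity* multiplies $b_{xy}$ by `group_ratio` in
cohorts labelled B. Per-SNP GWAS statistics are logistic Wald estimates by
IRLS (`glm.fit`) on case-control samples drawn retrospectively from a
simulated population; marginal log-odds ratios are invariant under
outcome-based sampling, so the GWAS/mQTL effect ratio at the causal SNP
converges to $b_{xy}$ up to the small logistic attenuation from the
non-genetic methylation variance (about 3% at the defaults). Effect
magnitudes are calibration choices — the source reports none — fixed once at
$\beta_{zx} = 0.5$ methylation units per allele and $b_{xy} = 0.4$ log-odds
per methylation unit: strong enough that instruments reliably clear
$5\times 10^{-8}$ at the default mQTL sample size (2,000), weak enough that
disease association stays realistic.

What the generator does *not* emulate: covariates (principal components,
birth year, sex) and family random effects in the cohort fits — those need
individual-level data and the pipeline consumes only summary statistics —
realistic genome-scale LD maps, imputation uncertainty, X-chromosome dosages,
or sample overlap between studies. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean causal simulation, not
robustness to confounding or structure in real cohorts.

All randomness flows from one integer seed through fixed stage offsets
(panel, mQTL, GWAS, per-probe), so any stage can be regenerated
independently; identical configuration and seed give bit-identical output.
Simulated studies place each probe in its own cis region, 4 Mb apart with 100
regions per chromosome, keeping cis windows disjoint and positions inside
integer range.

## Degenerate inputs, tie-breaks, validation

* Top-instrument ties: smaller mQTL $p$, then larger mQTL $|z|$, then smaller
  position — fully deterministic.
* $b_{zx} = 0$ is an error (undefined ratio); $b_{by} = 0$ gives
  $b_{SMR} = 0$, $T = 0$, $p = 1$ with a finite SE.
* Monomorphic SNPs are redrawn up to 10 times in the panel then excluded;
  monomorphic draws in a simulated sample, and separated or non-converged
  logistic fits, drop the SNP from that table with a message.
* Readers reject rows that violate record invariants ($a_1 \ne a_2$,
  $freq \in (0,1)$, $se > 0$, $p \in (0,1]$, cis window) with line numbers,
  returning the remainder; `strict = TRUE` escalates to errors. A row whose
  $p$ disagrees with $(b/se)^2$ by more than a factor of 2 draws a warning.
* All internal coordinates are 1-based inclusive; the BED reader/writer is
  the only 0-based half-open boundary. Empty gene fields serialize as `"."`
  so whitespace-delimited column counts are stable.
* The Bonferroni denominator defaults to the realized eligible-probe count;
  a fixed override (e.g. 91,000) reproduces a study-wide convention.

## Problem sizes used by the tests

The simulation-based checks run at sizes chosen to give stable operating
characteristics on a single CPU: type-I error over 500 null probes; effect
recovery and interval coverage over 200 pleiotropy replicates at study size
n = 5,000; HEIDI rejection over 500 replicates per scenario (25 cis SNPs,
mQTL n = 3,000, one 1,500/1,500 cohort); Wald calibration over 1,000
replicates; tail-probability validation on 10-20 random weight vectors with
200,000-draw Monte-Carlo references. The worked-example fixture tables under
`inst/extdata/` are published blood and brain scan rows used only to verify
printed-value consistency, never as inputs to estimation.

## Known limitations

Single-SNP instruments only (no multi-SNP SMR variants); no colocalization
methods beyond HEIDI; no genomic-control or sample-overlap correction in the
meta-analysis; no genome-build liftover; enrichment is a plain competitive
z-score, intentionally simpler than the external tool it stands in for.
Cross-group comparisons use each analysis's own instrument, so part of an
apparent effect difference can reflect instrument choice when tops differ
between analyses — both instruments are recorded in the outputs for exactly
this reason.
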
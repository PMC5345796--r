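---
title: "Methods: exhaustive two-locus interaction analysis of case-control SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustive two-locus interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistax)
```

# Overview

`epistax` implements an analysis pipeline for pairwise SNP interactions in
case-control genome-wide association data:

1. cohort input/output (PLINK bed/bim/fam) and standard quality control;
2. an exhaustive scan of all SNP pairs with a model-free
   discrimination-gain statistic, calibrated by permutation;
3. classification of the empirical two-locus penetrance models of
   significant pairs into canonical fully-penetrant classes;
4. likelihood-ratio tests of whether pairs carry information independent
   of known multi-allelic risk-haplotype dosages (the central confounder
   in the MHC, where strong haplotype structure can induce purely
   statistical interactions);
5. reduction of correlated pair signals to independent signals with a
   multi-allelic LD statistic (Hill's Q);
6. sparse L1-penalized squared-hinge predictive models over single-SNP
   dosages and pair indicators, with AUC evaluation, DeLong comparisons,
   and conversion of AUC to liability-scale variance explained.

A seedable synthetic-cohort generator with LD-block haplotype structure,
multi-allelic risk haplotypes and planted two-locus penetrance models
makes every stage testable at desk scale; the controlled-access data the
design emulates are never required.

# The pair statistic

For a SNP pair, samples fall into the 9 genotype combinations
(cell index $3 g_A + g_B + 1$). The scan asks whether those 9 cells
discriminate cases from controls *better than either SNP alone* — a
model-free notion of interaction that is insensitive to the scale
(additive, multiplicative) on which a regression test would have to be
specified.

The construction:

* Order the occupied cells by decreasing case:control odds, merging
  exact ties (cross-multiplied integer comparison). Prefix sets of this
  ordering are the candidate high-risk (HR) sets; by likelihood-ratio
  ordering their (sensitivity, false-positive-rate) points lie on the
  pair's ROC convex hull. The same construction on the 3 marginal
  genotype classes gives each single SNP's ROC hull.
* For a pair point $q = (TP_q, FP_q)$ and single SNP $m$, the *gain
  p-value* $g_m(q)$ is the probability that a classifier **no better
  than SNP $m$ alone** attains $q$'s sensitivity and specificity
  simultaneously:
  $$ g_m(q) = \max_{s} \; P[\mathrm{Bin}(n_1, \mathrm{sens}_s) \ge TP_q]
     \cdot P[\mathrm{Bin}(n_0, \mathrm{fpr}_s) \le FP_q], $$
  where $s$ ranges over the operating points available to such a
  classifier: the marginal hull vertices, the hull interpolation at
  $FP_q$ (a randomized mixture of adjacent vertices), and the pooled-rate
  diagonal point (a coin-flip classifier). Maximizing over $s$ is what
  makes the baseline honest: restricting $s$ to a single step point
  would let the "baseline" be a classifier that cannot produce positives
  at all, and the p-value would collapse to exactly zero — a degenerate
  statistic. With the maximization the statistic is strictly positive
  and computable in log space down to arbitrarily small values.
* The pair statistic is
  $p_{\mathrm{raw}} = \max_m \min_q g_m(q)$: the pair must beat **both**
  SNPs; the minimizing prefix set is the reported high-risk cell set,
  and the interaction odds ratio
  $OR = \frac{\pi_{1,HR}\,\pi_{0,LR}}{\pi_{0,HR}\,\pi_{1,LR}}$
  is computed from the within-phenotype HR/LR proportions.

The raw statistic is deliberately *not* treated as a calibrated
p-value. Under a pure null it is liberal (small values are over-produced
by the 9-cell optimization), which mirrors how the original
discrimination-gain statistic behaved on real data. The operative
contract is the **permutation calibration**: one or more full
permuted-label scans supply a null pool, a monotone quantile map is fit
on the $-\log_{10}$ scale (linear extrapolation beyond the deepest null
quantile), and observed values are mapped through it. On null cohorts
the adjusted p-values are uniform with genomic-control
$\lambda = 1.00$; the acceptance suite verifies this end to end.

Tie handling: cells and marginal classes with exactly equal odds are
merged into one ROC step, including the zero-control (infinite odds) and
zero-case groups. The prefix points of the merged ordering dominate any
sub-ordered intermediate points, so the statistic and the selected HR
set are unchanged by this simplification.

## Calibration resolution

Genomic-control $\lambda$ is the median adjusted chi-square quantile
over all pairs relative to the null median. Because every SNP
participates in $M-1$ pairs, the scan's p-values are dependent and the
median has far fewer effective degrees of freedom than the pair count:
at 500 SNPs the replicate-to-replicate standard deviation of $\lambda$
is about 0.07, at 1000 SNPs about 0.03. The calibration check therefore
uses 1000 independent SNPs (499,500 pairs) and pools three permuted-label
scans; the 500 case / 500 control sample sizes are kept. These choices
set only the Monte-Carlo resolution of the estimate — under the null
there are no effects for them to interact with.

# Quality control

SNP filters follow standard GWAS practice, applied in a fixed priority
order that assigns each removed SNP exactly one primary reason code:
non-autosomal, minor allele frequency below 5%, missingness above 1%,
then a two-sided exact Hardy–Weinberg test in controls at
$p < 5\times10^{-6}$ (conditional enumeration of heterozygote counts
given allele counts; no mid-p correction). Sample filters remove
missingness above 1%, then cryptic relatedness by a method-of-moments
identity-by-descent estimate on LD-thinned SNPs: for every pair with
$\hat\pi > 0.05$ the member with higher missingness is dropped (ties by
sample id).

Two numerical points about $\hat\pi$ that the package handles
explicitly. Plug-in allele frequencies bias the moment estimator upward,
so the expected-IBS terms use unbiased factorial-moment estimates of the
allele-frequency powers. And clamping each IBD component at zero before
summing turns symmetric noise into a positive bias for unrelated pairs,
so only the final $\hat\pi$ is clamped to $[0,1]$. A residual $O(1/n)$
bias remains because the tested pair's own alleles sit inside the
frequency estimates; at the panel depths where a 0.05 threshold is
meaningful (thousands of thinned SNPs) it is negligible.

# The synthetic cohort generator

The generator defines the "stated world" of all simulation-based tests.

* **Haplotype structure.** Each LD block has a pool of founder
  haplotypes (default 30) built by a first-order copying chain: the
  allele at the next SNP equals the previous one with probability
  $\sqrt{r^2_{\mathrm{target}}}$, else it is redrawn at the block
  frequency (drawn once per block from $U(0.1, 0.5)$). Individuals are
  mosaics of founders, recombining freely at block boundaries. This
  reproduces the two features the analysis cares about — within-block LD
  of a controllable level and a limited set of block haplotypes — without
  a coalescent simulator. With a target $r^2$ of 1 every block is a
  single perfectly linked unit, the degenerate case used in tests. What
  it does **not** emulate: recombination within blocks, mutation,
  demography, allele-frequency spectra; a green test on this world says
  the algorithms behave as specified, not that power estimates transfer
  to real MHC data.
* **Risk haplotypes.** Block 1 doubles as the risk-haplotype region:
  each founder carries one of $A$ multi-allelic labels (default 8,
  emulating imputed HLA-DQ alleles) and each individual's label counts
  form an $A$-column dosage matrix with per-allele log-odds effects.
  Because block-1 SNPs tag founder labels, SNP pairs in that block can
  be jointly associated with disease *through* the haplotype — the
  haplotype-induced interaction artifact that the independence filter
  must remove. `engineer_tagging = TRUE` plants the canonical version:
  two SNPs that each tag a diluted mixture of labels while their AND
  identifies the top-risk allele exactly.
* **Disease model.** On the logit scale, liability is a calibrated
  baseline plus risk-haplotype dosage effects plus, for each planted
  pair, $\mathrm{logit}(\mathrm{pen}[g_A, g_B]) -
  \mathrm{logit}(K)$, so a penetrance table equal to the prevalence
  everywhere contributes nothing. The baseline offset is root-found on a
  20,000-individual calibration sample so the superpopulation prevalence
  matches the configured value (default 1%); if the planted effects make
  the target unattainable the generator errors with the achievable range
  rather than silently re-weighting. Cases and controls are ascertained
  by batched rejection sampling with a hard cap.

Everything is reproducible from a single integer seed.

# Two-locus model classification

Empirical pair models use *balanced sample penetrance*
$P_v = p_{1v} / (p_{1v} + p_{0v})$, built from within-class cell
proportions so that the case:control sampling ratio cancels; 0.5 means
no association. Discretization to fully-penetrant (binary 3×3) models
forces cells rarer than 1% in both classes to low risk and thresholds
the rest at balanced penetrance 0.5 — the natural boundary of the
balanced scale; the published analyses state the binarization but not
the cut, and sweeping the rare-cell threshold between 0% and 7% leaves
the class distribution essentially unchanged, which the tests verify.

Canonical classes are orbits of the symmetry group generated by locus
swap (transpose), allele flip at either locus (row/column reversal) —
group order 8 — optionally extended by high/low risk complementation
(order 16). Exhaustive enumeration of all 512 tables gives 102 orbits
(100 excluding the two constant tables) without complementation and 51
(50 excluding the constant class) with it. The integer code is row-major
with locus A as rows and cell (0,0) as the most significant bit, so
published model-name conventions can be mapped onto class ids by a
lookup table; the engine treats names as opaque tags and none are
hard-coded.

# Conditional independence testing

Two nested-logistic likelihood-ratio tests:

* **Haplotype independence**: phenotype on risk-allele dosages (plus
  optional principal components) versus the same model plus the pair's
  cell indicators. A pair whose cells are captured by the haplotypes
  adds nothing and is filtered out; the retained set is controlled at
  FDR 5% by Benjamini–Hochberg (the p cutoff is data-dependent, never
  hard-coded).
* **Conditional interaction**: marginal SNP indicators plus optional
  dosages, principal components and strong-SNP covariates, versus the
  same plus the pair's interaction indicators. This detects interaction
  only on the log-odds scale — the regression counterpart to the
  model-free scan.

Encodings follow the dosage-plus-indicators convention: haplotypes as 8
real dosages, the pair as cell indicators with the most frequent control
cell as reference, marginal and conditioning SNPs as genotype
indicators. Two finite-count safeguards keep the chi-square reference
honest, both following the ten-events-per-parameter guidance for
logistic regression: a cell receives an indicator only if at least 10
cases and 10 controls carry it (others fold into the reference), and a
marginal homozygote class with fewer than 10 cases or controls collapses
to carrier (dominant) coding. Degrees of freedom are recomputed per pair
from the non-aliased columns actually added; aliased columns are dropped
deterministically in order of appearance. Complete separation triggers a
refit with a quadratic penalty of $10^{-4}$ on the slopes, flagged in
the result.

**Known limitation.** The implementation is numerically identical to
`glm()`'s deviance difference, and on cohort-scale samples with common
SNPs (MAF ≳ 0.1) its null distribution is uniform (verified by KS tests
across seeds). For pairs involving rare SNPs (MAF 0.05–0.10) the bulk of
the null distribution is mildly shifted (median p ≈ 0.42–0.47) even at
n = 4000, although tail rejection rates stay nominal; this is inherent
finite-count behaviour of multi-df likelihood-ratio tests, not removable
by further cell folding. The null-calibration demonstrations therefore
run on common post-QC SNPs, and rare-SNP conditional p-values near
conventional thresholds deserve caution.

Cross-cohort evidence combines by Fisher's method,
$X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$, with a $10^{-300}$ floor
required of the inputs (log-space p-values upstream). Population
structure is controlled with the top principal components of the
standardized, LD-thinned genotype matrix (deterministic sign
convention). Imputation quality of dosage columns is summarized by
INFO $= \mathrm{Var}(x) / (2p(1-p))$ in controls, 1 for hard calls at
Hardy–Weinberg proportions.

# Independent signals

Dependence between two SNP *pairs* is measured on phased control
haplotypes by treating each pair as one multi-allelic locus (its up-to-4
two-SNP haplotypes) and computing Hill's
$Q = \chi^2 / (2n)$ on the joint (≤4×4) table — the multi-allelic
extension of $r^2$, to which it reduces exactly in the biallelic case.
Cells with zero expected count contribute zero (the limit of the
chi-square term). $Q$ is used on the printed $\chi^2/(2n)$ scale, which
can exceed 1 for multi-allelic loci; the original normalization by
$(k-1)(l-1)$ is available as an option. Ranked pairs are pruned
greedily: accept the most significant pair, reject any later pair with
$Q > 0.3$ against an accepted one. The threshold is deliberately more
conservative than the $r^2 \le 0.5$ common in single-SNP pruning.

# Predictive models

Features are minor-allele dosages for single SNPs and 9 one-hot cell
indicators per pair (all-zero when either genotype is missing); the
consistent minor-allele orientation fixed at cohort load makes the
encoding transferable across cohorts, and external validation applies a
trained model without modification, with unseen features contributing
zero.

The model minimizes the L1-penalized squared hinge loss
$$ \tfrac{1}{2N}\sum_i \max\{0,\, 1 - y_i(x_i^\top\beta + \beta_0)\}^2
   + \lambda \lVert\beta\rVert_1 $$
by cyclic proximal coordinate descent with per-coordinate curvature
bounds $L_j = \tfrac1N \sum_i x_{ij}^2$ (the active-set curvature never
exceeds them, so the objective is non-increasing); tolerance $10^{-6}$
on the maximum coefficient change, at most $10^4$ sweeps. The penalty
grid spans $[10^{-4}\lambda_{\max}, \lambda_{\max}]$ in 100 log-spaced
values, where $\lambda_{\max}$ (all-zero solution) is computed
analytically after optimizing the intercept alone. Cross-validation is
class-stratified, warm-started along the path, and selects the penalty
maximizing mean held-out AUC (Mann–Whitney estimator, ties credited
one half). Paired AUCs are compared with DeLong's placement-value
covariance test.

AUC converts to liability-scale variance explained under the normal
liability threshold model at prevalence $K$ (default 1%): with
$t = \Phi^{-1}(1-K)$, $z = \phi(t)$, $i = z/K$, $i_2 = -z/(1-K)$,
$$ \mathrm{AUC}(h^2) = \Phi\!\left( \frac{h^2 (i - i_2)}
   {\sqrt{h^2\,(1 - h^2 i (i - t)) + h^2\,(1 - h^2 i_2 (i_2 - t))}}
   \right), $$
inverted by bisection to $10^{-6}$. This mapping, with prevalence and
AUC as its only inputs, reproduces every published (variance, AUC) pair
it is checked against to within the rounding of the published values.

# Replication workflow

Pair identity across cohorts is the unordered SNP-id pair. A validated
interaction pair must reach Bonferroni-adjusted significance
($\alpha / \binom{M}{2}$ over the panel's pair count) in the discovery
cohort and in at least one other cohort. Rankings order by adjusted p,
then raw p, then genomic position. Rank-overlap curves report
$|top_k(A) \cap top_k(B)| / k$; region tallies classify pairs as
both-inside / one-inside / both-outside a configurable interval
defaulting to the extended MHC span (chr6:25.6–33.4 Mb, the
conventional boundaries; the original analyses do not print exact
coordinates).

# Numerical and design choices not fixed by the published description

* Raw scan p-values live on the $\log_{10}$ scale end to end and cannot
  underflow; displayed `p_raw` may print as 0 below ~1e-308 but the
  `log10_p_raw` column is authoritative.
* The permutation quantile map's tail slope comes from the top
  percentile of the null pool; beyond the deepest null quantile the map
  is linear in $-\log_{10} p$.
* The relatedness tie-break (drop higher missingness, then
  lexicographically larger id) and the aliased-column drop order are
  deterministic so that repeated runs agree exactly.
* The greedy pruning order (descending adjusted significance, ties by
  position) is a design choice; only the statistic and threshold are
  fixed by the published description.
* Rejection-sampling ascertainment caps total draws and errors rather
  than accepting a biased partial sample.

# What the tests establish

Unit tests check each operation against independent oracles (exact
enumeration for Hardy–Weinberg and model-class counts, a slow
transliterated reference for the pair statistic, brute-force grid search
for the solver, bootstrap for DeLong, closed forms elsewhere);
property-style tests cover the symmetry, monotonicity and calibration
invariants; and the acceptance suite re-derives the published
quantities that are reproducible without the controlled-access
genotypes: the multiple-testing thresholds and pair counts implied by
the panel sizes, the 100/50 model-class counts, the liability-variance
values implied by the published AUCs, and calibration of the adjusted
scan on a null cohort. Everything else — the specific MHC findings, the
replication counts, the real-data AUCs — depends on data this package
deliberately does not require, and no test claims to reproduce it.
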
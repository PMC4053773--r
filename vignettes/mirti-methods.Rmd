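---
title: "Methods: biochemically anchored miRNA-target prioritization"
author: "mirti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biochemically anchored miRNA-target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A miRNA represses its targets through AGO-loaded seed pairing, but in tumor
expression data this repression is subtle: most predicted miRNA-target pairs
show correlations indistinguishable from background. `mirti` implements a
pipeline that anchors patient-cohort correlation analysis in biochemical
evidence: AGO2 PAR-CLIP binding sites identify which predicted interactions
are physically engaged, an elastic-net classifier generalizes that evidence
to expressed pairs the CLIP library may have missed, and gene-set
association, rank aggregation and survival models prioritize miRNA
regulatory activity within molecular subtypes.

This vignette documents the statistical machinery, the choices we made where
the design was genuinely open, and what the synthetic-data tests do and do
not establish.

# Site identification from PAR-CLIP reads

Reads longer than 20 nt that overlap by at least one base on the same
transcript are clustered by transitive single linkage, with no gap
allowance. Clusters with fewer than 5 reads or fewer than 20% crosslinked
(T-to-C-carrying) reads are discarded. The crosslink-centered region (CCR)
is the 41-nt window around the position with the most T-to-C conversions;
ties go to the 5'-most position, and windows running off a transcript end
are clipped, never padded (clipped CCRs are still scanned for sites). These
tie and edge rules are our own — the filtering thresholds themselves are the
standard ones for this assay.

Canonical seed sites are called per CCR and miRNA family (families share
seed positions 2–8 and are named by their lowest-numbered member): 8mer
(reverse complement of positions 2–8 followed by A), 7mer-m8, 7mer-1A, and
the perfect match to positions 1–7 when a mature sequence is available.
Each occurrence is reported once with its most specific type; an 8mer is
not double-counted as its constituent 7mers. The test suite holds the
caller equal to an independent brute-force substring scan over thousands of
randomized CCRs.

Sequence-composition significance uses dinucleotide-preserving shuffles
(Altschul–Erickson Eulerian-walk construction, implemented in C++ because
the null-calibration suites draw on the order of a million shuffles). For
each of the 16,384 7-mers we report the observed count over all CCRs, a
z-score against the shuffle null, an add-one empirical p-value
$(1 + \#\{\text{shuffle} \ge \text{obs}\})/(B+1)$, and Benjamini–Hochberg
q-values across the full 7-mer universe. Because the empirical p floors at
$1/(B+1)$, many null 7-mers can tie there; result rows are therefore
ordered by (q, then descending z), which is also how "most enriched" is
defined throughout.

# Abundance thresholds and the correlation shift

miRNA abundance is the relative read frequency (RRF: a miRNA's reads over
the sample's total); microarray mRNA abundance is
$A = \log_2\sqrt{R \cdot G}$; sequencing mRNA is RPKM with per-sample
zero-replacement before log2. Defaults follow the thresholds established
for these data: RRF $> 10^{-4}$ for miRNAs and $A > 6.5$ for array mRNA;
sequencing mRNA uses a detection filter only (more than 20 reads in at
least 5% of samples; miRNAs use more than 10). The detection filter is
strict ("more than") and the sample fraction is a ceiling. Probe
condensation averages probes whose pairwise correlations all exceed 0.8;
groups failing that rule fall back to the highest-mean probe — the paper
trail for this step specifies only the averaging rule, so the fallback and
the all-pairwise reading are our choices (configurable).

Family expression is the sum of member RRFs, which preserves the RRF scale;
a max-member alternative is available. The central statistic is the
difference of medians between the Pearson correlation distribution of
predicted miRNA-target pairs and that of all remaining family-gene pairs,
tested with a two-sided Wilcoxon rank-sum (exact below 50 per group). A
negative shift means targets are more anti-correlated than background.
Threshold sweeps recompute the shift over abundance grids; subtype analyses
recompute it within each subtype's samples.

# The PAR-CLIP-like classifier

Candidate pairs are TargetScan-style predictions whose family and gene pass
the abundance thresholds and whose gene owns at least one retained cluster.
Positives are additionally seed-matched within a CCR; negatives are
crosslinked but not seed-matched — so both classes have biochemical
support for the gene, and the model learns what distinguishes engaged
pairs. The 16 features are the prediction table's conservation and context
scores, the six per-type site counts with their two totals, and
expression-derived terms (family mean/variance, gene mean/variance, and
signed/unsigned abundance interaction products; the signed term uses the
sign of mean log2 fold-change and collapses to the unsigned term for
sequencing data without fold-changes).

The model is a binomial elastic net (glmnet). The LASSO/ridge mix is not
pinned down by its description ("combination of LASSO and ridge"), so we
default to $\alpha = 0.5$ and cross-validate the penalty only, which is
common glmnet practice; features are standardized and the transform stored.
The train/test split is stratified 50/50 (the reported counts imply roughly
half for training); a gene-grouped split is available to avoid leakage,
since whether the original split was structured is unstated. Pairs without
crosslink evidence never enter training but are scored at prediction time —
that is what produces "additional" targets. The MP-PCLIP set is the union
of PAR-CLIP-evidenced pairs and model predictions at a posterior cutoff of
0.5, each pair tagged `parclip`, `model` or `both`. AUC uses the rank
statistic with midranks; PPV(c) is TP/(TP+FP) among pairs scoring at least
c, and FDR = 1 − PPV.

# The permutation global test

For response $y$ and standardized covariates $x_1 \dots x_m$, the statistic
is the mean squared score against the intercept-only residuals $r$:

$$Q = \frac{1}{m} \sum_{j=1}^m (x_j^\top r)^2$$

with $r$ the centered response (linear), $y - \bar y$ (logistic), stacked
one-vs-rest indicator residuals (multinomial — the reference formulation
names multinomial regression without a formula, so we sum the one-vs-rest
logistic statistics), or null martingale residuals from the Nelson–Aalen
baseline (Cox). Significance comes from permuting $r$ across samples with
the add-one rule, so the test is exact under exchangeability for every
response kind, rather than relying on the asymptotic distribution used by
the original gene-set test implementation. $B$ defaults to 9,999 and every
call is seeded. $Q$ is invariant to covariate order and sign flips, and the
suite checks agreement with exhaustive enumeration at $n = 7$ and nominal
type-I error for the linear, logistic and Cox modes.

Pathway association runs one test per (family, gene set) with the family's
expression as response and the set members as covariates, BH-corrected
within family; associations are flagged when the set contains an MP-PCLIP
target of the family, and flagged associations are compared to unflagged
ones with a one-sided Welch t-test on $-\log_{10} p$. Ranking combines
three evidence sources per family — its own-target test, the smallest p
over MP-PCLIP-containing sets, and the cancer-gene-set test — by equal-
weight mean rank (ties averaged, missing evidence worst-ranked). The rank
test's reference describes no formula, so significance is our
reimplementation choice: each evidence column is permuted independently
across families and a family's p is the add-one fraction of permutations
with a combined score at least as small. Phenotype ranking uses the same
aggregation over up to six clinical tests (logistic: nodal status and
lymphovascular invasion; multinomial: size class and grade; Cox: metastasis
and overall survival), with the family's own expression included among the
covariates (a flag excludes it; the source description is loose on this
point). Prognostic signatures are the Cox-mode test of a family plus its
targets; adjusted mode replaces the null residuals with martingale
residuals from a clinical Cox model, asking what the signature explains
beyond grade, size and nodal status.

# The synthetic study

The generator emits every input the pipeline reads, with ground truth.
Defaults are the conditions the recovery tests run under: 100 genes with
60/240/400-nt 5'UTR/CDS/3'UTR structure, 20 families with distinct 7-nt
seeds, two subtypes of 40 samples, 3 active families per subtype, 8 targets
per family. Planted 8mer sites are written into target 3'UTRs in slots
spaced 60 nt apart (beyond the maximum read span, so clusters for different
families never merge), each with a crosslinkable T two bases upstream.
Repression acts on log2 expression proportionally to the regulator's
per-sample RRF over its cohort mean, scaled by `beta` (default 1, noise
`sigma` = 0.25) — so higher-expressed regulators repress more, which is the
structure the abundance-threshold analysis assumes. Library sizes are
log-normal so RRF genuinely differs from raw counts. The PAR-CLIP library
carries per-read crosslink probability 0.8 (the mRNA-read conversion rate
reported for this assay), plus seedless background clusters and
sub-threshold decoys so the filter paths are always exercised. Prediction-
table features for true pairs are shifted by a configurable effect (default
1 SD) against a Poisson/Gaussian baseline; survival is exponential with
hazard ratio 2 per SD of the signature score and uniform censoring;
phenotypes follow logistic/ordinal links.

What the synthetic data does not emulate: read sequencing errors, isomiRs,
copy-number structure, non-canonical (seedless) sites, platform-specific
array saturation, and patient heterogeneity beyond subtype labels. Passing
recovery tests therefore demonstrates the statistical machinery —
calibration, power under the stated effect sizes, and exact bookkeeping —
not performance on real cohorts.

# Numerical choices and problem sizes

Empirical p-values always use the add-one rule, so they are never zero and
never below $1/(B+1)$. Zero-variance covariates are dropped with a warning
(correlations and point-biserial associations report NA instead).
Zero-shuffle-variance k-mers get z = 0. The per-analysis sample handling
drops incomplete phenotype rows locally, never globally. The test suite
runs its calibration loops at deliberately compact sizes — for example
1,000 null simulations at 20–30 samples for the shift and global tests, 50
ranking replicates at 60 samples, and 200 null survival replicates at 100
samples — chosen to keep Monte-Carlo error within the asserted tolerance
bands; the acceptance script reports the problem size next to every number
it emits.

# Known limitations

The Wilcoxon comparison of correlation distributions treats pair
correlations as exchangeable between the target and background groups;
correlations sharing a family or gene are dependent, so the test is
calibrated for label exchangeability (which the null simulations verify)
but is not an independence test. The multinomial global-test statistic
weights one-vs-rest components equally. The elastic-net posterior is a
ranking device, not a calibrated probability, away from the 0.5 operating
point. And the permutation global test prices in covariate correlation
under the null but, like any score test, loses power when only a small
subset of a large covariate set carries signal.
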
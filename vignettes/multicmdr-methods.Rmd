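---
title: "Cluster-based MDR for multiple quantitative traits: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based MDR for multiple quantitative traits: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicmdr)
```

## The problem

Complex traits are shaped not only by single-locus effects but by gene–gene
interactions (epistasis). Multifactor dimensionality reduction (MDR) methods
search for interacting SNP sets by pooling the $3^m$ multilocus genotype
cells of an $m$-SNP combination into two risk groups, reducing the
combination to a single binary attribute that can be scored and
cross-validated. Most MDR variants handle one phenotype; in practice a
disease is often characterized by several correlated quantitative traits
(e.g. lipid panels: HDL, LDL, triglycerides), and analyzing them jointly can
reveal pleiotropic interactions that per-trait analyses miss.

`multicmdr` implements a multivariate, cluster-based MDR. Its distinctive
ingredient is how samples are divided into the two reference groups used to
label genotype cells: instead of thresholding a summary score, it fuzzily
clusters the standardized phenotype vectors into two groups plus a *noise
cluster* that absorbs outliers, and carries the (soft) membership degrees
through the cell-labeling step. This makes the procedure robust to outliers
and to skewed phenotype distributions.

## The procedure

Given $n$ samples with genotype vectors $X_i \in \{0,1,2\}^p$ (additive
coding) and phenotype vectors $Y_i \in \mathbb{R}^q$:

**Standardization.** Each trait is centered and scaled to unit sample
standard deviation. Constant traits are an error: they carry no information
and break the scaling.

**Noise-cluster fuzzy c-means.** Standardized phenotypes are partitioned by
fuzzy $k$-means with $k = 2$ plus a virtual noise prototype sitting at a
constant squared distance $\delta$ from every sample. Memberships
$M_{ik} \ge 0$ ($k = 1, 2, 3$; cluster $C_1$, $C_2$, noise) with
$\sum_k M_{ik} = 1$ and centers $c_1, c_2$ minimize

$$J_{\text{Noise}} = \sum_{i=1}^n \sum_{k=1}^2 M_{ik}^m \lVert x_i - c_k
\rVert^2 + \sum_{i=1}^n \delta\, M_{i3}^m ,$$

where $m > 1$ is the fuzzifier. A sample far from both centers (squared
distance $\gg \delta$) accumulates noise membership rather than dragging a
center toward it. We set $\delta$ to the average squared Euclidean distance
over all unordered sample pairs — about $2q$ for uncorrelated standardized
traits — so "outlier" means "further from both centers than a typical
between-sample distance". Optimization is the standard alternating scheme;
each half-step minimizes the objective exactly, so $J_{\text{Noise}}$ is
nonincreasing (asserted in the tests to $10^{-9}$).

**Trimming and the global ratio.** Samples whose noise membership is their
strict row maximum are removed (a tie with a good cluster retains the
sample — the conservative choice). For retained samples, two-cluster
memberships are recomputed from the fitted centers by the standard fuzzy
c-means rule
$M_{ik} = 1 / \sum_{j=1,2} (\lVert x_i - c_k \rVert^2 / \lVert x_i - c_j
\rVert^2)^{1/(m-1)}$, so each row again sums to one, and the global ratio
$\theta = \sum_i M_{i1} / \sum_i M_{i2}$ is computed once on the full
retained set. Relabeling the clusters maps $\theta \mapsto 1/\theta$ and
leaves everything downstream invariant.

**Cell labeling and scoring.** Retained samples are split into $N$
cross-validation folds (seeded shuffle, sizes differing by at most one).
For each candidate SNP set and each training fold, the local ratio
$\theta_j$ of cell $j$ is the ratio of summed $C_1$ to summed $C_2$
memberships of the training samples in that cell; the cell is labeled $D_1$
iff $\theta_j \ge \theta$ (so a cell with positive $C_1$ mass and zero
$C_2$ mass, $\theta_j = \infty$, is $D_1$). Every sample inherits its
cell's label, and the separation of the $D_1$/$D_2$ phenotype groups is
scored by Hotelling's two-sample $T^2$ with the pooled covariance. The best
model per fold maximizes training $T^2$; cross-validation consistency (CVC)
counts the folds in which a SNP set wins; the final best model maximizes
CVC, and its test-fold $T^2$ values are averaged into the reported
statistic. Significance comes from a permutation test that shuffles whole
phenotype rows (preserving trait correlations) and re-runs the *entire*
pipeline — clustering included — on each permuted dataset; the p-value is
the fraction of null statistics strictly exceeding the observed one.

**Baselines.** Two comparison methods share the fold assignment, the cell
machinery and the CVC logic bit for bit, isolating the methodological
difference to the labeling rule and statistic: QMDR labels cells by
comparing the local mean of one trait to its global training mean and
scores with a squared pooled $t$; multi-QMDR projects the standardized
traits on the first principal component (FPC) of the training-fold
covariance, labels cells by FPC means, and scores with $T^2$. With one
trait, multi-QMDR reduces exactly to QMDR (asserted in tests).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| fuzzifier $m$ | 2 | membership softness; 2 is the conventional choice |
| $\delta$ | mean pairwise squared distance | noise-cluster squared distance (unitless after standardization) |
| restarts | 5 | seeded k-means++-style restarts; best final objective kept |
| tol / max_iter | $10^{-6}$ / 300 | convergence on max membership change |
| folds $N$ | 10 | cross-validation folds |
| order $m$ | 2 | interaction order (exhaustive search over $\binom{p}{m}$ sets) |
| $B$ | 0 (off) | permutations for the empirical p-value |

Degenerate cases are handled deterministically: a sample exactly on a
center receives full membership there; exact equidistance gives equal good-
cluster memberships; empty training cells — and test cells unseen in
training — are labeled $D_2$ (the neutral default in the MDR literature);
an invalid statistic (empty group, $n_1 + n_2 - 2 < q$, singular pooled
covariance) scores $-\infty$ and can never be selected; CVC ties break by
larger mean training $T^2$, then lexicographically smallest SNP set.

## The synthetic-data generator

The simulation design mirrors the conditions under which this class of
methods is usually evaluated: $n = 400$ samples, $p = 20$ independent SNPs
in Hardy–Weinberg proportions (genotype $\sim$ Binomial(2, MAF), MAF preset
0.2 or 0.4), a causal pair (SNP1, SNP2 by convention) acting through a
$3\times3$ penetrance table $f_{ij}$, two phenotypes, and 100 replicate
datasets per condition with 10-fold CV.

Two phenotype families share the location structure (cell mean $f_{ij}$ for
both traits, unit variance, correlation $\rho \in \{0, 0.25, 0.5\}$):

* **bivariate normal**: $Y \mid \text{cell}(i,j) \sim \mathrm{MVN}((f_{ij},
  f_{ij})^T, \Sigma)$ with $\Sigma = \bigl(\begin{smallmatrix} 1 & \rho \\
  \rho & 1 \end{smallmatrix}\bigr)$;
* **bivariate gamma via a Gaussian copula**: latent $(z_1, z_2) \sim
  \mathrm{MVN}(0, \Sigma)$, $u_k = \Phi(z_k)$, $y_k = F^{-1}(u_k)$ with $F$
  the Gamma(shape $f_{ij}^2$, scale $1/f_{ij}$) CDF — marginal mean
  $f_{ij}$, variance 1, skewness $2/f_{ij}$, and Spearman correlation
  $(6/\pi)\arcsin(\rho/2)$. The scale (not rate) parameterization is the
  one that gives unit variance, matching the normal family; the rate
  reading would give variance $f_{ij}^4$ and mean $f_{ij}^3$, breaking the
  design's comparability across cells.

Penetrance tables are parameterized rather than enumerated: a `null`
(constant) table, an `xor` checkerboard (interaction-driven; no marginal
effects at MAF 0.5) and a `threshold` table, each with a gain factor that
`calibrate_gain()` solves analytically for a target heritability
$h^2 = \mathrm{Var}(f)/(\mathrm{Var}(f) + 1)$ under the HWE cell
probabilities. The baseline effect level is 1 so the same table is valid
for the gamma family (which needs $f_{ij} > 0$). What the generator does
*not* emulate: linkage disequilibrium among SNPs, missing genotypes,
covariates, more than two traits (the engine itself accepts any $q \ge 1$),
and non-exchangeable null SNPs — so passing tests demonstrate calibration
and power under idealized sampling, not robustness to structured real data.

## Design choices where the design was open

* **Clustering before cross-validation.** Standardization, clustering,
  trimming and $\theta$ are computed once on all samples; folds then split
  the retained set, and only the *local* ratios are recomputed per training
  fold. The train/test information sharing this implies is inherent to the
  procedure's ordering of steps, not an implementation shortcut; the null
  calibration experiment confirms it does not bias pair selection.
* **Membership formula after trimming.** The two-cluster membership is the
  standard fuzzy c-means expression with the fitted centers held fixed
  (no refit after removing noise samples).
* **$\delta$ convention.** $\delta$ is the mean pairwise *squared* distance
  and enters the objective linearly as the noise prototype's squared
  distance; as $\delta \to \infty$ the fit converges to plain two-cluster
  fuzzy c-means (checked numerically at $\delta = 10^8$).
* **FPC fitting.** The multi-QMDR loading is estimated on each training
  fold only and applied to its test fold, avoiding test leakage; its sign
  is fixed so the largest-magnitude entry is positive, which also makes the
  tied-eigenvalue case deterministic.
* **Permutation scheme.** Each permuted dataset re-runs the full pipeline
  (clustering included), since the permuted phenotypes define a new
  clustering problem; the p-value uses the strict inequality, with no +1
  correction, so under the null it is uniform on $\{0, 1/B, \dots, 1\}$.
* **Null-data generation.** Both permutation of a causal dataset's
  phenotype rows (default, matching how empirical false-positive rates are
  usually computed for this design) and direct simulation from a constant
  table are supported.

## Problem sizes used in the validation suite

The test suite validates calibration and power at the design scale where
that is what is being claimed, and at reduced scale where the claim is
about the machinery: the null selection rate uses 2000 null datasets at the
full $n = 400$, $p = 20$ design (the designated pair should win
$1/\binom{20}{2} \approx 0.0053$ of the time); the power comparisons use
100 replicate datasets at full scale; permutation-test calibration uses 200
replicates of a scaled-down problem ($n = 100$, 5 SNPs, 5-fold CV, 2
clustering restarts, $B = 99$) because its subject is the uniformity of the
p-value under the null, which does not depend on the problem size; and
generator moments use single draws of $n = 50{,}000$.

## Limitations

Exhaustive search scales as $\binom{p}{m}$: practical for the few hundred
pre-filtered SNPs this method targets, not genome-wide. The clustering step
assumes two phenotype groups are a meaningful working partition; phenotypes
with one homogeneous mode still yield a valid (if uninformative) split, and
heavily multimodal phenotypes are better served by transforming first. The
$T^2$ statistic needs $n_1 + n_2 - 2 \ge q$ within every fold, so many
traits with small folds will produce invalid models. P-values from the
permutation test are conditional on the selection procedure and should not
be reused for other model ranks without re-running the test.
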
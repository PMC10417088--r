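---
title: "Estimating immune cell composition in liver tumors: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating immune cell composition in liver tumors: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immdeconv)
```

## The problem

A bulk expression profile of a liver tumor biopsy mixes RNA from the tumor
cells with RNA from the immune cells infiltrating the microenvironment.
Cell composition deconvolution (CCD) recovers the per-cell-type proportions
from that mixture. `immdeconv` models the bulk profile over a set of
signature genes as a non-negative linear combination of reference
cell-type profiles,

$$ b_i \;=\; \sum_{j=1}^{17} a_{ij}\, x_j, \qquad x_j \ge 0, $$

where $b_i$ is the bulk expression of signature gene $i$, $a_{ij}$ is the
median expression of gene $i$ in cell type $j$ from a labelled reference
panel, and $x_j$ is the unknown proportion of cell type $j$. Two design
choices distinguish this workflow from generic immune deconvolution:

1. **The tumor is a column of the signature.** HCC cells dominate most
   biopsies; if they are absent from the reference, their expression leaks
   into the immune estimates ("spillover"). Estimating the tumor fraction
   explicitly and then discarding it (renormalizing the 16 immune fractions
   to sum to one) makes immune composition comparable across samples with
   different tumor content.
2. **Polarized subtypes are first-class.** The panel separates three M1 and
   three M2 macrophage induction forms, naive from memory CD8 T cells, and
   four CD4 lineages (naive, Treg, Th1, Th2), because differently polarized
   forms of the same lineage can have opposite prognostic associations.

## Building the signature matrix

Closely related subtypes (the M1 forms, the M2 forms, the two B-cell and two
CD8 subsets, the CD4 lineage, NK/DC) have strongly correlated profiles, so a
single 17-way differential-expression screen mostly recovers genes that
separate the distant lineages. Ranking is therefore run within **seven
groups**: the all-types group plus six correlated subsets (see
`hcc_cell_groups()`). Within each group every gene gets a classical
equal-variance one-way ANOVA F-test across the group's cell types, and genes
are sorted by ascending p-value.

Two numerical details matter:

* **Ties at p = 0.** When replicate noise is very low, many genes have zero
  within-type variance: their F statistic is infinite and the p-value is
  exactly zero, so the p-value ordering is vacuous. Such genes are ordered
  by their between-type sum of squares — the ordering that F itself
  converges to as within-type variance vanishes. Without this rule the
  selection would be arbitrary in near-noise-free data.
* **How many genes per group.** The top-$g$ genes of each group are pooled
  (duplicates collapse, so the union is usually smaller than $7g$). The
  per-group count $g$ is chosen by scanning `sweep_range` (default 8–24,
  centered on the default $k = 16$) and keeping the candidate whose median
  signature matrix has the smallest 2-norm condition number
  $\kappa = \sigma_{\max}/\sigma_{\min}$; ties go to the smaller $g$. A
  lower $\kappa$ means the regression solution is less sensitive to
  perturbations of the bulk profile. $\kappa$ is computed exactly from the
  singular values (a matrix with $\sigma_{\min} < 10^{-12}\sigma_{\max}$ is
  treated as rank deficient and excluded).

An optional `min_expression_floor` drops genes whose best per-type median is
below a threshold; the default (0) keeps the ranking purely p-value-driven,
since the ANOVA on grouped subsets already targets genes elevated in
specific types.

## The regression models

`deconvolve()` offers five solvers behind one interface; all end with
negative coefficients clipped to zero and the result renormalized to
fractions summing to one.

* **ε-SVR** (default): linear epsilon-insensitive support vector regression
  (via `e1071`), the field-standard core for signature-based CCD. Residuals
  inside the ε tube carry no loss, which gives robustness against
  gene-level noise; the L2 penalty on the coefficient vector (weight $C$)
  stabilizes correlated columns. The signature and bulk are z-scored over
  the signature genes before fitting, which makes the estimated fractions
  invariant to the overall scale of the bulk profile. Exposed defaults are
  ε = 0.1, C = 1 (standardized units). **The tube width should match the
  residual noise one expects**: for benchmark suites of exactly (or almost
  exactly) representable mixtures the package's own evaluations use a
  near-interpolating setting, ε = 0.001, C = 1, which on the synthetic
  conditions below dominates the wide-tube default at *every* noise level.
* **Relative-error regressions** (`l1`, `l2`, `elastic_net`): minimize the
  mean relative absolute error plus a penalty,
  $$ \frac{100}{n}\sum_{n} \frac{|b_n - \hat b_n|}{b_n}
     \;+\; \alpha \sum_j x_j \;+\; \beta \sum_j x_j^2,
     \qquad x \ge 0 . $$
  Genes with $b_n = 0$ are excluded from the sum (the relative error is
  undefined there); these fits run in raw linear space because the
  objective itself divides by $b_n$. The non-smooth objective is solved by
  projected L-BFGS-B on a lightly smoothed absolute value
  ($|r| \approx \sqrt{r^2 + \delta^2}$, $\delta = 10^{-6}$), started from
  the non-negative least-squares solution; on random 6-gene systems the
  solution matches a brute-force grid search over the probability simplex
  (step 0.005) to ~1e-11 per coordinate.
* **`lasso`**: standard non-negative L1-penalized least squares via
  `glmnet`, on the same standardized data as the SVR.

### Significance of a fit

The Monte-Carlo test asks whether the Pearson correlation between the
observed bulk and its reconstruction $\hat b = A x$ could arise by chance.
The bulk sample's values are permuted across its **full gene universe**
(not just the signature genes), each permuted profile is re-deconvolved,
and $p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\})/(n_{\text{perm}}+1)$
with ties counted as exceedances — the conservative add-one permutation
estimator. Permuting over the full universe is the default because the
alternative (permuting within the signature genes only) leaves the null
profiles confined to the signature's expression range and is slightly
anticonservative on heavy-tailed data.

## The synthetic study conditions

Real reference panels and tumor cohorts cannot ship with the package, so
`generate_reference_dataset()` emulates the structure that matters for the
method:

* 17 cell types with the reference panel's replicate counts (204 profiles:
  19 tumor + 185 immune, at least 4 per type);
* each type's log-scale profile is a unit-variance mixture of a
  type-specific component and, within each correlated subset, a shared
  latent component with weight `within_subset_correlation` (default 0.6) —
  so related types are genuinely hard to separate while unrelated types are
  uncorrelated;
* 30 disjoint marker genes per type, up-regulated `marker_fold_change`-fold
  (default 8), out of 2000 genes;
* replicates are the base profile times i.i.d. log-normal noise
  (`noise_sigma`, default 0.2 on the natural-log scale — a typical
  replicate coefficient of variation for expression arrays).

`generate_benchmark_suite()` then builds spike-in bulk mixtures: for each
tumor-fraction level $P \in \{15, 30, 45, 60, 75, 90\}\%$ it draws one
tumor replicate and one replicate per immune type, assigns immune weights
from a flat Dirichlet scaled to $1 - P$, and sums the profiles with those
weights. Ground truth and the consumed replicate ids are recorded (so an
evaluation can rebuild the signature without the source replicates, though
the default evaluation scores against the full-reference signature).

What the generator does **not** model: per-gene baseline heterogeneity
shared across cell types (housekeeping structure), microarray background
and saturation, RNA-seq count noise and library-size effects, and
platform-specific probe effects. Passing the synthetic benchmarks therefore
demonstrates that the estimator recovers compositions whose generative
model matches its assumptions; it does not certify performance on any real
platform, where cross-platform normalization (`tpm_transform()`,
`quantile_normalize()`, `cross_platform_scale()`) and residual model
mismatch dominate the error budget.

## Problem sizes used in the shipped evaluations

The packaged tests and `scripts/acceptance.R` run a scaled-down version of
the full protocol: 20 mixtures per tumor-fraction level (120 per noise
level) across generator noise $\sigma \in \{0, 0.05, 0.1, 0.2\}$; the full
204-sample leave-one-out pure-cell protocol; 200 noise-only and 50
mixture-derived profiles for Monte-Carlo calibration at 99 permutations.
These sizes give stable medians while keeping a complete evaluation run in
minutes. On these conditions the noise-free suite is recovered with median
per-sample $r \ge 0.99$ at every tumor level, every held-out pure sample is
assigned to its own cell type (median dominant fraction ~0.87), the
Monte-Carlo null rejects at the nominal 5% rate, and every
signature-derived mixture passes $p < 0.05$. The leave-one-out protocol
rebuilds each signature with a singleton sweep at $k = 16$; rerunning the
full condition-number sweep inside every holdout changes no conclusion and
triples the cost.

## Decisions where the design was genuinely open

* **Quantile normalization of reference and query**: applied separately per
  dataset by default (`quantile_normalize()` on each matrix); the CLI and
  functions accept jointly concatenated matrices when a shared reference
  distribution is preferred.
* **Duplicate gene ids** on input are collapsed by row-wise mean and logged.
* **Cross-platform adjustment** is a single global linear factor matching
  the query maximum to the reference maximum; a per-quantile mapping is
  deliberately not attempted, so sample-sample correlations are untouched.
* **Median split ties** go to the "low" group (high means strictly above
  the median).
* **Cox ties** use the Efron approximation.
* **The two-sided Fisher test** uses the point-probability criterion.
* **Risk groups** from multi-etiology clinical flags use a documented
  precedence (HBV > HCV > alcohol), configurable.
* **Immune mixing weights** in the simulator are flat-Dirichlet; one
  replicate per component is drawn rather than averaging replicates.
* **TMB high/low**, where needed, is a cohort-median split (no absolute
  threshold is assumed).

## Known limitations

* The signature construction assumes linear-scale, already gene-summarized
  expression; probe-level microarray preprocessing is out of scope.
* Fractions are relative, not absolute cell counts; comparisons across
  samples assume similar total RNA per cell across types.
* With fewer usable genes than cell types the relative-error fits are
  underdetermined and only warn.
* The Monte-Carlo permutation null ignores gene-gene correlation; its
  calibration was verified on independent-gene nulls.
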
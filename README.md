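# immdeconv

Cell composition deconvolution for bulk expression profiles of
hepatocellular carcinoma (HCC): estimate the proportion of tumor cells and
sixteen immune cell types — including polarized macrophage forms (three M1
and three M2 induction states), naive vs memory CD8 T cells, and the CD4
lineage (naive, Treg, Th1, Th2) — from a genes × samples expression matrix.
It is aimed at computational oncologists relating tumor-microenvironment
immune composition to survival, mutational burden, and treatment response.

## The model

The bulk profile `b` over a set of signature genes is modeled as a
non-negative mixture of reference cell-type profiles:

```
b_i = Σ_j a_ij · x_j ,   x_j ≥ 0,  j = 1 … 17
```

`a_ij` is the median expression of signature gene `i` in cell type `j`,
taken from a labelled reference panel; `x` is the vector of cell-type
proportions. The signature matrix is built by ranking genes with one-way
ANOVA inside seven cell-type groups (all 17 types plus six correlated
subsets such as the M1 forms or the two CD8 subsets), pooling the top genes
per group, and choosing the per-group count that minimizes the matrix's
2-norm condition number κ = σ_max/σ_min — a low κ makes the regression
robust to noise in the bulk profile. The default solver is linear
ε-insensitive support vector regression with an L2 coefficient penalty;
relative-error regressions with L1/L2/elastic-net penalties and
non-negative lasso are available behind the same interface. Tumor content
is estimated explicitly as a 17th component and then removed, with the
sixteen immune fractions renormalized to sum to one, so immune composition
is comparable across samples with different tumor purity. A permutation
(Monte-Carlo) test assesses the significance of each fit.

Because the reference microarray panel and tumor cohorts cannot ship with
the package, a synthetic-data module generates labelled reference panels
(17 types, 204 replicate profiles, planted markers, correlated subsets,
log-normal replicate noise) and spike-in bulk mixtures with known ground
truth at tumor fractions from 15% to 90%, plus the scoring and survival
statistics used downstream (Kaplan–Meier/log-rank, univariate Cox, Welch
t-test, Fisher exact test, min–max survival scaling).

## Worked example

```r
library(immdeconv)

## labelled synthetic reference panel: 2000 genes x 204 replicate profiles
ref <- generate_reference_dataset(synthetic_reference_config(seed = 7))

## signature construction with condition-number minimization
sig <- optimize_signature(ref$expression, ref$annotation)
sig
#> signature matrix: 143 genes x 17 cell types, kappa = 8.331 (top 24 genes per group)

## one spike-in mixture with 60% tumor content, then deconvolve it
suite <- generate_benchmark_suite(ref$expression, ref$annotation,
                                  levels = 0.6, n_per_level = 1, seed = 42)
res <- deconvolve(sig, suite$mixtures[, 1], n_perm = 99, seed = 1)
res
#> deconvolution result (epsilon_svr): fit r = 0.9762, coverage = 1.00
#> Monte-Carlo p = 0.01
#>    HCC  M1_IFNg  M1_IFNg_TNF  M1_LPS  M2_IL4_Dex   ...
#> 0.5900   0.0115       0.0000  0.0469      0.0281   ...

round(sort(remove_tumor_and_renormalize(res$fractions), decreasing = TRUE)[1:5], 3)
#>      Th1 B_memory   M1_LPS  B_naive     Treg
#>    0.151    0.151    0.114    0.110    0.098
```

The estimated tumor fraction is 0.59 against a ground truth of 0.60; the
fit correlation 0.976 and Monte-Carlo p = 0.01 say the reconstruction is
far better than any permuted profile; the immune-only fractions (after
tumor removal) correlate with the true mixing weights at r = 0.98.

A command-line wrapper with subcommands `simulate`, `build-signature`,
`deconvolve`, `benchmark`, `assoc`, and `demo` is installed at
`system.file("cli", "immdeconv", package = "immdeconv")`; every run writes
a `manifest.json` with options, seed, and input checksums.

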
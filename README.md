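# stoichiomap

Linking dimension-reduced single-cell Raman spectra to condition-dependent
omics profiles, and extracting the global **stoichiometry conservation
architecture** of gene expression.

The package is aimed at systems biologists and spectroscopists who have
(or simulate) two paired datasets: a genes × conditions non-negative
abundance matrix, and single-cell spectra measured under the same
conditions. It answers two questions:

1. **Can low-dimensional spectral patterns predict the omics profile?**
   Spectra are preprocessed (background subtraction, 632–1862 cm⁻¹ crop,
   Savitzky–Golay smoothing, per-spectrum standardization, 700–1800 cm⁻¹
   fingerprint band), classified by condition with linear discriminant
   analysis (m conditions → m−1 axes), and the affine model
   `p̂_j = B [1; r̂_j]` is fitted per gene by OLS and validated by
   leave-one-out cross-validation over conditions with a permutation test
   of the overall error `Σ_j dist(p̂_j, p̂_j^est)`.
2. **What constrains the omics profiles to so few dimensions?** All-pairs
   cosine similarity of expression vectors `A_ij = cos θ(p_i, p_j)` defines
   a weighted complete graph. Thresholded components (`A_ij ≥ 0.995`) are
   stoichiometrically conserved groups (SCGs); the weighted degree
   `d_i = Σ_j A_ij` is the stoichiometry conservation centrality; the
   L1/L2 norm ratio `g_i = ‖p_i‖₁/‖p_i‖₂ ∈ [1, √m]` is the expression
   generality. Laplacian eigenmaps of `L_rw = I − D⁻¹A` give the
   proteome structure Ω_LE; intercept-normalized regression coefficients
   `β_ik = b_ik/b_i0` give the Raman-based structure Ω_B. Their agreement
   is quantified by the orthogonal alignment matrix Θ (closeness to the
   identity, scored against Haar-random orthogonal matrices) and by the
   proportionality `d_i ≈ ((Σ_j d_j)/m)^{1/2} · g_i`.

A fully deterministic synthetic-data generator plants this structure
(growth-law core, condition-specific SCGs, unstructured background, linear
protein-to-spectrum map) so the whole chain is testable end to end without
any downloads. Annotation statistics (binned essentiality fractions,
one-sided Brunner–Munzel rank tests between top and bottom centrality
quartiles) connect centrality to gene attributes supplied as tables.

## Worked example

```r
library(stoichiomap)
cfg <- pipeline_config(
  generator = generator_config(n_proteins = 300, core_size = 60,
                               specific_group_sizes = c(20, 12, 8),
                               cells_per_condition = 6, replicates = 2,
                               channel_count = 300, seed = 1),
  n_perm = 2000, n_null = 300, seed = 1)
report <- run_pipeline(cfg, outdir = "stoichiomap-out")
```

```
inputs: proteome 300 x 15, 180 cells x 300 channels
preprocess: 267 channels retained
lda: 14 axes, |r|(LDA1, growth) = 0.982
correspondence: K = 4, permutation p = 0.0005
network: 4 SCGs (sizes 60, 20, 12, 8)
comparison: theta closeness 0.291 (null percentile 100.0)
annotation: 300 genes joined
```

Reading the log: 15 conditions give exactly 14 discriminant axes and the
first one tracks growth rate (|r| = 0.98) — the growth-law core dominates
the spectra. Held-out condition profiles are predicted well enough that
none of 2000 random condition permutations beats the matched assignment
(p = 0.0005, the smallest value 2000 permutations can certify). The four
planted SCGs are recovered at the 0.995 cosine threshold with their exact
sizes (60, 20, 12, 8). The Θ matrix relating the embedding- and
regression-based proteome structures scores closeness 0.29 to the
identity, above all 300 Haar-random orthogonal matrices. The report also
carries the d–g proportionality (analytic slope 66.6 here) and the
Spearman correlation of its residuals with the growth rate of each
protein's most-expressed condition (ρ = 0.81): proteins above the line are
expressed most under fast growth.

Every stage is also available as a standalone function
(`preprocess_spectra`, `fit_lda`, `fit_b`, `loocv`, `permutation_test`,
`cosine_matrix`, `extract_scgs`, `generality`, `csle`, `compute_theta`,
`theta_closeness`, `d_g_proportionality`, `subsample_conditions`,
`brunner_munzel`, …); tables are read and written as TSV
(`read_proteome_tsv`, `read_spectra_tsv`, …) and the pipeline report as
JSON.

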
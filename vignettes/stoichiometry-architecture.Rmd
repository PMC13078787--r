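---
title: "Stoichiometry conservation architecture from spectra-omics correspondence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometry conservation architecture from spectra-omics correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichiomap)
```

## The problem

Cells adapt their molecular composition to their environment while keeping
core physiology stable. Single-cell Raman spectra are superpositions of the
vibrational signatures of all molecules in a cell, so systematic
condition-dependent differences in global spectral patterns carry
information about the underlying expression profile. `stoichiomap`
implements an analysis chain that (i) validates a *linear* statistical
correspondence between dimension-reduced Raman spectra and
condition-dependent omics profiles, and (ii) uses that correspondence, and
the omics data alone, to expose a global architecture of *stoichiometry
conservation*: groups of gene products whose mutual abundance ratios stay
nearly constant across conditions.

## The model

With $m$ conditions and $n$ protein species, write $\hat{r}_j$ for the
mean $(m-1)$-dimensional LDA representation of single-cell spectra under
condition $j$ and $\hat{p}_j$ for the condition's expression profile. The
correspondence hypothesis is affine-linear,

$$\hat{p}_j = B \begin{bmatrix} 1 \\ \hat{r}_j \end{bmatrix},$$

with a condition-independent $n \times m$ coefficient matrix $B$, fitted
per protein by ordinary least squares (minimum-norm when underdetermined)
and validated by leave-one-out cross-validation over conditions plus a
permutation test of the overall prediction error
$\sum_j \mathrm{dist}(\hat{p}_j, \hat{p}^{\mathrm{est}}_j)$.

The stoichiometry-conservation side works on the per-protein expression
vectors $p_i \in \mathbb{R}^m_{\ge 0}$:

* **Similarity network**: $A_{ij} = \cos\theta_{p_i p_j}$, a weighted
  complete graph with unit loops; thresholded connected components
  ($A_{ij} \ge 0.995$) are the stoichiometrically conserved groups (SCGs),
  the largest being the growth-law *homeostatic core*.
* **Centrality**: $d_i = \sum_j A_{ij}$, the weighted degree, with
  $1 \le d_i \le n$.
* **Generality**: $g_i = \lVert p_i\rVert_1 / \lVert p_i\rVert_2 \in
  [1, \sqrt{m}]$ — 1 for one-hot (condition-specific) expression,
  $\sqrt m$ for uniform expression.
* **csLE embedding**: eigenvectors of the random-walk normalized Laplacian
  $L_{\mathrm{rw}} = I - D^{-1}A$; the $m-1$ nontrivial eigenvalues lie
  strictly in $(0,1)$ and the corresponding eigenvectors are the
  coordinates ($\Omega_{\mathrm{LE}}$).
* **Regression-based coordinates** ($\Omega_{\mathrm{B}}$):
  $\beta_{ik} = b_{ik}/b_{i0}$; perfectly conserved proteins share one
  point.

The two $m$-dimensional augmented representations (trivial/constant axis
prepended) are related by a linear map whose orthogonal polar factor
$\Theta$ must be close to the identity for the two structures to agree,
together with a second condition equivalent to proportionality between
$d_i$ and $g_i$ with analytic slope $\left(\sum_j d_j / m\right)^{1/2}$.
Closeness of $\Theta$ to the identity is scored by the weighted Pearson
correlation of coordinates $(i, j)$ with weights $\Theta \circ \Theta$
(total mass exactly $m$ for an orthogonal matrix) and referenced against
Haar-random orthogonal matrices.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| crop / band | 632–1862 / 700–1800 cm⁻¹ | wide crop, then fingerprint band for classification |
| SG window / order | 11 / 3 | Savitzky–Golay smoothing (channels / polynomial degree) |
| `K` | 4 | leading LDA axes used in the correspondence fit |
| `threshold` | 0.995 | cosine threshold defining SCG edges |
| `n_perm` | 10⁴ (pipeline), 10⁵ supported | permutations for the error test |
| `n_null` | 1000 | Haar draws for the Θ null |
| intercept tolerance | 1e-8 × median(\|b₀\|) | proteins excluded from Ω_B |

Distances available for validation: squared Euclidean (PRESS, the
default), Manhattan, cosine distance, and 1 − Pearson.

## What the synthetic generator emulates

`make_proteome()`/`make_spectra()` generate data with the structure the
analysis targets, at the reference scale $n = 2058$, $m = 15$, with 15
cells × 3 replicates per condition on a 1 cm⁻¹ grid:

* a **growth-law core** (191 proteins) with expression $a_i\,\mu_j$
  (protein amplitude × growth rate, zero intercept) — the within-group
  cosine is exactly 1 at zero noise;
* a **fast-growth group** (26 proteins) with $a_i \exp(b\,\mu_j)$, $b$
  set for a ~30-fold dynamic range over the growth-rate span;
* smaller **condition-peaked groups** (20, 10, 9 proteins) with a shared
  single-condition peak over a 5% baseline;
* **background proteins** with independent lognormal condition patterns
  (sdlog 0.5), i.e. unstructured variation smaller than the >10-fold
  planted program responses;
* multiplicative lognormal abundance noise with CV 0.05, the replicate
  reproducibility scale of high-quality absolute proteomics;
* spectra $S\,p_j\,\eta + \varepsilon$ with a fixed non-negative signature
  matrix (3–8 Gaussian peaks per protein on the fingerprint band, widths
  8–25 cm⁻¹), per-cell lognormal intensity scale (sdlog 0.05) and additive
  channel noise (sd 0.02 of a unit-sd clean spectrum).

Amplitudes are lognormal (sdlog 1) around a common scale, and the core is
given a 3× amplitude boost so that it carries a dominant mass share, as
ribosomal/information-processing proteins do in real biomass; this is what
lets the first discriminant axis track growth rate, mirroring the
growth-law premise.

What the generator does **not** emulate: real Raman band assignments
(signatures are abstract), instrument noise structure (no pixel-dependent
readout noise), baseline drifts or cosmic rays, biological intercepts in
the growth law, and correlations between background proteins. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted structure under realistic noise — not that any
particular organism's data will show the same effect sizes.

## Numerical choices

* **LDA with more channels than cells**: the data are first projected onto
  the span of the total scatter (singular values above 1e-10 relative);
  the within-class scatter there is still rank-deficient
  (rank ≤ cells − classes), so its pseudo-inverse square root is used as
  the whitening metric. If the within-scatter vanishes entirely
  (duplicated cells), the unit metric on the total-scatter span is used.
  Axis signs are fixed by making the largest-magnitude loading positive.
* **csLE** is solved through the symmetric form $D^{-1/2}AD^{-1/2}$ and,
  because $A = NN^\top$ has rank at most $m$, through the $m \times m$
  problem on $N^\top D^{-1} N$ — exact, stable and linear in $n$.
  Eigenvectors are unit-norm with the same sign convention as LDA.
* **Minimum-norm fits** use the Moore–Penrose pseudo-inverse, so
  leave-one-out fits with $K = m - 1$ (14 equations, 15 unknowns) have
  exactly zero training residuals.
* **Permutation test**: the $m \times m$ table of distances between
  measured and predicted profiles is precomputed, so each permutation is
  an index lookup; permutations are drawn uniformly with replacement
  (identity included) and $p = (1 + \#\{\text{null} \le
  \text{obs}\})/(1 + n_{\mathrm{perm}})$.
* **Ω_B exclusions**: proteins with $|b_{i0}|$ below 1e-8 × median or
  exactly zero are excluded rather than propagated as unstable ratios.
* **Θ**: polar factor (SVD $UV^\top$) of the least-squares map between
  the augmented representations over shared proteins; orthogonality is
  asserted to 1e-8 on every call. Per-axis positive rescaling of either
  representation does not change the polar factor.
* **Brunner–Munzel**: pooled midranks, Satterthwaite-type degrees of
  freedom; complete separation gives an infinite statistic with the
  limiting 0/1 one-sided p-value, and only fully tied pooled samples are
  rejected as degenerate.
* **Condition subsampling**: the Haar null of the closeness score
  concentrates as the matrix grows, so raw closeness values at different
  subset sizes are not comparable; precision is reported as closeness
  standardized by the size-matched null mean and sd (raw values are kept
  alongside).

## Design choices at genuinely open points

* Standardization is applied on the wide 632–1862 cm⁻¹ crop and the
  700–1800 cm⁻¹ band is selected afterwards; the reverse order is
  available via `standardize_before_band = FALSE`.
* Sample (n−1) standard deviation in standardization; at ~10³ channels the
  difference from the population form is negligible.
* The coefficient matrix used for coefficient-level analyses defaults to
  the average of the leave-one-out estimates; a single full-data fit is
  available (`theta_b_estimate = "full"`) and gives indistinguishable
  results on synthetic data.
* Group-level coefficient proportionality reports per-axis slopes and
  R² through the origin plus a pooled R² over all axes; the pooled value
  is the meaningful summary because per-axis R² is a noise-to-noise ratio
  on axes whose true slope is near zero.
* SCG components use a closed threshold (ties at 0.995 included), minimum
  reported size 2, ordered by size with ties broken by smallest member
  index.

## Problem sizes used by the test suite

The packaged tests run the full chain at $n = 300$, $m = 15$, 12 cells per
condition and 300 channels — the same planted structure as the reference
scale at a size where the whole suite completes in well under a minute —
and exercise the full $2058 \times 15$ scale where the quantity under test
depends on it (matched-scale SCG sizes, the $d_i = n$ bound). Calibration
properties (permutation-test size, Brunner–Munzel size) use 200 and 2000
replicates respectively.

## Known limitations

* The Θ construction is an operational definition via the polar factor of
  the protein-level least-squares map; closed-form derivations of the
  relation between the two spaces are not reproduced here.
* LOOCV validates condition-level (population-averaged) profiles;
  single-cell expression inference is out of scope.
* Annotation statistics consume user-supplied tables; no database
  retrieval is performed.
* With non-negative data all cosine similarities are positive, so the
  nontrivial Laplacian eigenvalues cluster near 1 and the ordering of weak
  tail modes is sensitive to noise; conclusions should rest on the leading
  axes and on null-referenced scores, as the pipeline reports them.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(generator = generator_config(seed = 1),
                       n_perm = 10000, seed = 1)
report <- run_pipeline(cfg, outdir = "stoichiomap-out")
str(report$theta)
```
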
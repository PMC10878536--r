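---
title: "POPLS-DA: model, estimation, and workflow design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{POPLS-DA: model, estimation, and workflow design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poplsda)
```

## The problem

Cell-line studies frequently measure several omics layers — say a
transcriptome and a proteome — on *disjoint* groups of samples, with a shared
case/control contrast (for example, cells overexpressing a disease protein
versus a control protein). Because the samples do not overlap, the usual
horizontal integration through cross-omics correlations is unavailable.
What the layers do share is the variable namespace: transcripts and proteins
can both be mapped to gene identifiers. Vertical integration stacks the
datasets row-wise on that shared namespace and asks which genes jointly
discriminate cases from controls across all layers.

`poplsda` implements a probabilistic orthogonal partial-least-squares
discriminant model for this setting, together with the full surrounding
workflow: preprocessing, feature prioritisation, permutation inference,
drug-target network integration, and over-representation analysis.

## The model

For dataset $k = 1, \dots, K$, each sample's centered expression vector
$x_k \in \mathbb{R}^p$ and outcome $y_k \in \mathbb{R}$ are modelled as

$$
x_k = W u_k + P_k v_k + e_k, \qquad
y_k = \beta^\top u_k + \epsilon_k,
$$

with all random variables zero-mean Gaussian and independent:

* $u_k \in \mathbb{R}^r$ — **joint** latent components, shared loading matrix
  $W$ ($p \times r$) across all datasets; only these carry the association
  with the outcome.
* $v_k \in \mathbb{R}^{r_k}$ — **dataset-specific** components with loadings
  $P_k$, absorbing structured variation private to one layer (platform
  effects, dataset-specific biology).
* $e_k \sim N(0, \sigma^2_{e,k} I_p)$ and
  $\epsilon_k \sim N(0, \sigma^2_\epsilon)$ — residual noise.

The per-feature **effect size** is the composition $W\beta$; its squared
elements rank features by their contribution to the case/control contrast.
Binary group labels are encoded $y = +1/2$ (case) and $-1/2$ (control) — a
zero-mean coding consistent with the Gaussian outcome; classification
thresholds the predicted score at zero, with ties going to control.

### Identifiability conventions

The likelihood is invariant to invertible mixing between loadings and latent
covariances. The package fixes the canonical representative with

* diagonal latent covariances ($\Lambda_u = \mathrm{diag}(\sigma_u)$,
  $\Lambda_{v_k}$) and isotropic residuals per dataset;
* column-orthonormal $W$ and $P_k$, with $\sigma_u$ sorted non-increasing;
* each column's largest-magnitude loading positive (signs absorbed into
  $\beta$).

Orthogonality *between* $W$ and $P_k$ is not enforced; with $r + r_k \ll p$
random subspaces are nearly orthogonal anyway, and leaving the constraint
out keeps every M-step closed-form. Fitted loading matrices should therefore
be compared by principal angles between column spans (see
`principal_angles()`, `recovery_metrics()`), never elementwise.

## Estimation

`poplsda()` maximises the observed-data likelihood of $(x, y)$ jointly by
expectation–maximization. Everything is *memory-efficient*: the implied
covariance

$$
\Sigma_{x,k} = W \Lambda_u W^\top + P_k \Lambda_{v_k} P_k^\top
  + \sigma^2_{e,k} I_p
$$

is never materialised. All solves, quadratic forms and log-determinants go
through the Woodbury identity and the matrix determinant lemma with a core
of size $r + r_k (+1)$ (`implied_covariance()` and friends), so fitting
$p$ in the thousands with a handful of components costs
$O(N p (r + r_k))$ per iteration and stores nothing larger than
$p \times (r + r_k + 2)$.

* **E-step.** Per sample, posterior first and second moments of the stacked
  latent vector $(u_k, v_k)$ given $(x, y)$, via one Cholesky factorisation
  of the $(r + r_k)$-dimensional posterior precision per dataset.
* **M-step.** Closed-form conditional maximisation: $W$ (shared) and all
  $P_k$ solve the coupled normal equations jointly given the current
  variances; then $\beta$, then all variances given the new loadings.
  Conditional ordering preserves the EM ascent guarantee; the test suite
  asserts a non-decreasing log-likelihood trace on every seeded run.
* **Canonicalisation.** After each iteration a thin SVD of
  $W \Lambda_u^{1/2}$ (and of each $P_k \Lambda_{v_k}^{1/2}$)
  re-orthonormalises the loadings, absorbing the mixing into the latent
  variances and $\beta$ — an exact, likelihood-invariant
  reparameterisation, so monotonicity is untouched.
* **Multi-start.** Local optima are mitigated by `n_starts` seeded
  initialisations (default 5): the first is spectral, from a Gram-matrix
  ($N \times N$, never $p \times p$) low-rank decomposition of the stacked
  data; the rest are random orthonormal frames. The best final likelihood
  wins. On small problems the EM optimum matches direct numerical
  maximisation of the dense likelihood (BFGS from 10 random starts) to
  $10^{-4}$, which the acceptance suite verifies.

Numerical guards: variance parameters are floored at $10^{-12}$; the small
linear systems carry a $10^{-10}$ ridge; convergence is declared when the
relative log-likelihood change drops below `tol` (default $10^{-6}$,
`max_iter` 1000).

Prediction conditions on $x$ only ($\hat y = \beta^\top E[u \mid x]$),
while training conditions on $(x, y)$ — the natural split between fitting
and scoring when labels are what the score must reproduce.

## Preprocessing

Real inputs go through `preprocess_stack()`:

1. **Mapping and intersection** (`map_and_intersect()`): platform features
   are renamed to gene identifiers; when several platform features map to
   one gene, the highest-variance one is kept (the mapping choice most
   common in expression work; any aggregation rule can be applied upstream
   instead); datasets are restricted to the genes present in every layer,
   sorted lexicographically.
2. **Optional IQR filter** (`iqr_filter()`): keeps features whose
   inter-quartile range exceeds the median feature IQR — removing the
   flat half of the features before mapping.
3. **Sign harmonisation** (`harmonize_signs()`): vertical integration
   assumes each gene's effect points the same way in every layer. Per
   feature, the Welch two-sample $t$ statistic (case minus control) is
   compared in sign against a chosen reference layer and discordant columns
   are negated. Only the sign is used, so the $t$ variant is immaterial
   except exactly at zero, where the feature is left unflipped with a
   warning. The flip mask is returned so the transform is auditable and
   reapplicable.
4. **Standardisation** (`standardize_stack()`): per dataset and feature to
   zero mean and unit variance (unbiased $n-1$ denominator), with centers
   and scales stored for scoring new data.

Choosing $r$ and $r_k$ is guided by `scree_eigenvalues()` — eigenvalues of
the sample covariance of the row-wise concatenated stack, computed from the
$N \times N$ Gram matrix — but the defaults $r = r_k = 2$ are sensible for
two-layer designs and the helper is advisory only.

## Feature selection

`rank_features()` sorts features by squared effect size (stable sort, ties
broken lexicographically — selection is fully deterministic).
`elbow_index()` automates the visual elbow rule as the index maximising the
perpendicular distance to the chord joining the first and last points of
the sorted curve, first index on ties, warning on constant curves. A manual
`n` in `select_top()` overrides the elbow, which is how a fixed selection
size (e.g. the top 200 genes of a real analysis) is reproduced.

## Permutation inference

Perfect training accuracy by itself proves nothing at $p \gg N$;
`permutation_test()` calibrates it. For each of $B$ permutations the group
labels are shuffled *within* each dataset (preserving the per-dataset
case/control counts — the exchangeability structure of a vertically
integrated design), and the full pipeline is refit from scratch: model fit,
top-$n$ selection, refit on the selected features, training accuracy on the
permuted labels. The p-value is the fraction of permutations reaching
accuracy 1 — the plain `n_perfect / B` convention, under which one perfect
permutation in 400 reads 0.0025; a conservative
`(n_perfect + 1) / (B + 1)` variant is available behind a flag. Each
permutation runs on its own seeded substream, so results are reproducible
and invariant to permutation order. Per-permutation refits default to a
single spectral start with a looser tolerance: the accuracy statistic needs
a representative fit, not a fully polished one, and the observed pipeline
is run under the identical options.

## Drug-target network integration

`load_network()` reads a tab-separated edge list with optional confidence
scores, keeping edges at or above a threshold (default 0.4, the usual
medium-confidence cutoff), canonicalising the undirected pairs and dropping
self-loops. `expand_targets()` performs the direct-neighbor expansion: each
drug's target set is augmented with all genes adjacent to a target — a
depth-1 breadth-first step. `count_links()` then intersects the expanded
sets with the relevant (selected) genes, producing the per-gene drug counts
(halo intensities) and per-drug interactor counts. Targets count as their
own interactors when inside the relevant set by default;
`exclude_self_targets = TRUE` counts strict neighbors only, since published
summaries are ambiguous between the two readings. The bipartite handshake
identity (gene-side total = drug-side total) is asserted in the tests.

## Over-representation analysis

`fisher_enrichment()` computes, per term set, the one-sided hypergeometric
upper tail $P(X \ge \text{overlap})$ — the Fisher exact test of
over-representation — against a user-supplied background, followed by
Benjamini–Hochberg adjustment across all terms of the run (one annotation
source per run). Mid-p corrections are not used. Term sets come from
standard GMT files (`read_gmt()`); the background defaults to the analysed
feature universe, and published genome-wide backgrounds can be supplied as
plain gene lists.

## The synthetic-data generator

`simulate_stack()` draws stacks exactly from the generative model with
known ground truth: seeded substreams per dataset, joint loadings supported
on `support_size` designated features (so truly relevant features are
known), and group labels obtained by thresholding the continuous latent
outcome $y^* = \beta^\top u + \epsilon$ at zero.

Two design choices deserve explanation:

* **Separation margin.** Thresholding a continuous Gaussian at zero always
  produces samples arbitrarily close to the boundary, and under orthonormal
  loadings the posterior precision of $u$ given $x$ is capped at
  $1/\sigma^2_e$ — so *no* latent-variance scale makes perfect training
  accuracy attainable. Real case/control conditions are two distinct
  experimental states, not a razor-thin threshold. The generator therefore
  accepts a `margin` (in sd units of $y^*$): samples inside the band are
  redrawn. The two-omics preset uses margin 1.
* **Analysis scale.** Simulated stacks are already zero-mean on the model's
  own scale and are analysed as-is. Re-standardising them would estimate
  per-column scales from as few as 6 samples, injecting multiplicative
  noise that breaks the shared-loading structure across layers.
  Standardisation remains the documented preprocessing step for real data,
  where scales genuinely differ.

`luhmes_config()` is the preset mirroring the motivating study's shape: two
layers on disjoint samples (6 transcriptome + 18 proteome samples),
$r = r_k = 2$, and latent variances sized so that roughly a fifth of each
layer's variance is joint and a quarter dataset-specific, with $p$
defaulting to 500 for tractable test runs (real studies have a few thousand
shared genes; the model's cost is linear in $p$). `fixture_network()`
provides seeded Erdős–Rényi interaction networks and drug-target maps for
the integration modules.

## What the tests do and do not show

The test suite runs entirely on synthetic data, at these problem sizes:
EM ascent on 20 seeded configurations ($p \le 22$); equivalence with direct
numerical maximisation at $p = 8$, $N = 15$; Woodbury-versus-dense checks
for 50 random parameter draws up to $p = 50$; ground-truth recovery at
$p = 200$, $N_k = 50$, 10 seeds (mean principal angle below 10°, effect
correlation above 0.9, selection precision/recall at least 0.95 at high
SNR, $\sigma^2_e = 0.02$); permutation calibration with $B = 99$ over 20
null replicates at $p = 60$ and a strong-signal run at the study shape
($p = 500$, $N = 6 + 18$); network and enrichment oracles on dozens of
random instances; and bit-level reproducibility of the full workflow.

Passing these demonstrates correctness of the *computations* under the
model's own assumptions. It does not certify behaviour under model
violations real data bring: non-Gaussian expression, correlated residuals,
batch effects, count noise, missing features across layers (explicitly
unsupported), or annotation bias in network and term databases.

## Known limitations

* One binary outcome; no missing values; residuals isotropic per dataset.
* The latent covariance structure (diagonal) and the absence of a
  $W \perp P_k$ constraint are one canonical choice within the model
  family; other parameterisations of the same likelihood exist.
* Variance decompositions at very small $N_k$ (e.g. 6 samples) are noisy:
  dataset-specific components partially absorb residual variance, inflating
  the specific fraction. The joint fraction is estimated more stably.
* The permutation test uses training accuracy as its statistic by design —
  it tests the null of no label–feature relation, not out-of-sample
  performance.
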
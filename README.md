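# poplsda

Vertical integration of multi-omics case/control data with a probabilistic
OPLS discriminant model.

Cell-line studies often measure several omics layers — a transcriptome and a
proteome, say — on *disjoint* samples, with the same experimental contrast
(cases overexpressing a disease protein versus controls). The layers cannot
be correlated sample-by-sample, but they share a gene namespace, so the
datasets can be stacked row-wise. `poplsda` models such a stack with a joint
Gaussian latent-variable model (POPLS-DA): for dataset *k*,

```
x_k = W u_k + P_k v_k + e_k        y_k = β'u_k + ε_k
```

where the joint components `u_k` (shared loadings `W`, p × r) carry the
case/control association, the dataset-specific components `v_k` (loadings
`P_k`) absorb variation private to a layer, and `e_k`, `ε_k` are Gaussian
noise. The per-gene effect size is `Wβ`; its squared elements rank genes.
Parameters are fitted by memory-efficient maximum likelihood — an EM
algorithm whose linear algebra runs through low-rank-plus-diagonal
(Woodbury) identities with a core of size r + r_k, so no p × p matrix is
ever formed.

Around the model, the package provides the full workflow:

* **Preprocessing** — platform-to-gene mapping with intersection across
  layers, IQR variance filtering, cross-layer effect-sign harmonisation,
  per-dataset standardisation (`preprocess_stack()` and parts).
* **Feature prioritisation** — squared-effect-size ranking with an
  automated elbow rule and manual top-n override (`rank_features()`,
  `select_top()`).
* **Permutation inference** — stratified label permutations with full
  pipeline refits; the p-value of perfect discrimination is the fraction of
  permutations reaching accuracy 1 (`permutation_test()`).
* **Drug-target network integration** — direct-neighbor expansion of drug
  target sets in a protein-protein interaction network and drug/gene link
  counts (`load_network()`, `expand_targets()`, `count_links()`).
* **Over-representation analysis** — one-sided hypergeometric (Fisher)
  tests against GMT term sets with BH correction (`fisher_enrichment()`).
* **Synthetic data** — seeded simulation from the generative model with
  known ground truth, plus network/drug fixtures (`simulate_stack()`,
  `luhmes_config()`, `fixture_network()`).
* **Orchestration** — `run_workflow()` drives all stages from one YAML
  config; `inst/cli/poplsda.R` is a thin command-line wrapper.

Results come back as tibbles; fitted objects support `tidy()`, `glance()`,
`augment()` and `autoplot()`.

## Worked example

Simulate a two-layer stack shaped like a small cell-line study (6
transcriptome + 18 proteome samples, 300 shared genes, known relevant gene
set), fit the model, select genes, and calibrate the discrimination by
permutation:

```r
library(poplsda)

cfg <- luhmes_config(p = 300, seed = 11)
sim <- simulate_stack(cfg)

fit <- poplsda(sim$stack, r = 2, r_k = 2, seed = 11)
fit
#> <poplsda_fit> p = 300 , r = 2 , r_k = [ 2, 2 ]
#>   log-likelihood: -9269.541 after 132 iterations (converged)
#>   transcriptomics: 37.5% joint, 38.5% specific, 24.1% residual
#>   proteomics: 36.4% joint, 28.6% specific, 35.0% residual

ranking <- select_top(rank_features(fit), n = 36)
head(ranking, 4)
#> # A tibble: 4 x 5
#>    rank feature  effect effect_sq selected
#>   <int> <chr>     <dbl>     <dbl> <lgl>
#> 1     1 g0212   -0.0125  0.000156 TRUE
#> 2     2 g0267    0.0121  0.000147 TRUE
#> 3     3 g0263   -0.0114  0.000130 TRUE
#> 4     4 g0213   -0.0110  0.000120 TRUE

perm <- permutation_test(sim$stack, B = 99, seed = 12, r = 2, r_k = 2,
                         n_select = 36)
perm
#> <permutation_result> B = 99
#>   observed training accuracy: 1
#>   permutations with perfect accuracy: 0
#>   empirical p-value: 0
```

The fit prints the variance decomposition per layer: the joint fraction is
variance explained by the components shared across layers (the part carrying
the case/control signal), the specific fraction is private structured
variation, the rest is residual noise. The observed pipeline separates cases
from controls perfectly (training accuracy 1) while none of the 99
label-permuted refits do — an empirical p-value of 0 (at most 1/99) for the
null of no label–gene relation.

The selected genes are strongly enriched for the simulation's planted
relevant set:

```r
fisher_enrichment(selected_features(ranking),
                  list(true_support = sim$support),
                  sim$stack$feature_ids)
#> # A tibble: 1 x 7
#>   term         term_size overlap query_size background_size  p_value      fdr
#>   <chr>            <int>   <int>      <int>           <int>    <dbl>    <dbl>
#> 1 true_support        36      28         36             300 3.55e-25 3.55e-25
```

28 of the 36 selected genes are truly relevant (hypergeometric
p ≈ 3.6e-25 against the 300-gene background).

## Documentation

The methods vignette (`vignettes/poplsda-methods.Rmd`) describes the model
and its assumptions, the EM algorithm and its identifiability conventions,
every tunable parameter with its default and rationale, the design of the
synthetic-data generator, and known limitations.
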
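Package: poplsda
Title: Probabilistic OPLS Discriminant Analysis for Vertically Integrated Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertical integration of multi-omics expression data from
    case/control cell-line experiments with a probabilistic orthogonal
    partial-least-squares discriminant model (POPLS-DA). Datasets measured on
    disjoint samples but sharing a gene namespace are stacked row-wise and
    modelled with shared joint latent components that carry the association
    with group status, plus dataset-specific components and Gaussian noise.
    Parameters are estimated by memory-efficient maximum likelihood (an
    EM algorithm working through low-rank-plus-diagonal covariance
    identities), features are prioritised by squared effect size with an
    elbow rule, and perfect case/control discrimination is tested by label
    permutation. Companion tools integrate a drug-target table with a
    protein-protein interaction network by direct-neighbor expansion, run
    hypergeometric over-representation tests with BH correction, simulate
    stacks from the generative model with known ground truth, and
    orchestrate the full workflow from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
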
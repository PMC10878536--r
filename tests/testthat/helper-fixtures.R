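# Small builders shared across tests. Everything is generated in code.

toy_dataset <- function(values, id = "omics1",
                        groups = rep(c("case", "control"),
                                     length.out = nrow(values))) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(id, "_s", seq_len(nrow(values)))
  }
  omics_dataset(values, id, groups = groups)
}

# a deterministic two-dataset stack with both groups in each layer
toy_stack <- function(p = 6, n1 = 6, n2 = 8, seed = 42) {
  set.seed(seed)
  d1 <- toy_dataset(matrix(rnorm(n1 * p), n1, p), "omics1",
                    groups = rep(c("case", "control"), each = n1 / 2))
  d2 <- toy_dataset(matrix(rnorm(n2 * p), n2, p), "omics2",
                    groups = rep(c("case", "control"), each = n2 / 2))
  omics_stack(list(d1, d2))
}

# small valid random parameter set (dense dataset-specific loadings)
toy_params <- function(p = 6, r = 2, r_k = c(1, 2), seed = 1,
                       ids = c("omics1", "omics2")) {
  set.seed(seed)
  W <- random_orthonormal(p, r, seed = seed)
  rownames(W) <- paste0("g", seq_len(p))
  P <- list(); sv <- list()
  for (i in seq_along(ids)) {
    if (r_k[i] > 0) {
      P[[ids[i]]] <- random_orthonormal(p, r_k[i], seed = seed + i)
      sv[[ids[i]]] <- sort(runif(r_k[i], 0.5, 2), decreasing = TRUE)
    } else {
      P[ids[i]] <- list(NULL)
      sv[[ids[i]]] <- numeric(0)
    }
  }
  poplsda_params(
    W = W, P = P, beta = rnorm(r),
    sigma_u = sort(runif(r, 1, 3), decreasing = TRUE), sigma_v = sv,
    sigma2_e = setNames(runif(length(ids), 0.3, 1.2), ids),
    sigma2_eps = runif(1, 0.2, 1)
  )
}

# dense multivariate normal log-density at zero mean (independent oracle)
dense_mvn_loglik <- function(obs, Sigma) {
  # obs: d x n matrix of column observations
  R <- chol(Sigma)
  z <- backsolve(R, obs, transpose = TRUE)
  n <- ncol(obs)
  -0.5 * (n * (nrow(obs) * log(2 * pi) + 2 * sum(log(diag(R)))) + sum(z^2))
}
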
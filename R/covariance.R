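#' Implicit low-rank-plus-diagonal covariance of (x, y) under the model
#'
#' The model implies, for dataset k,
#' \deqn{\Sigma_x = W \Lambda_u W' + P_k \Lambda_{v_k} P_k' + \sigma^2_{e,k} I,}
#' \eqn{Cov(x, y) = W \Lambda_u \beta} and
#' \eqn{Var(y) = \beta' \Lambda_u \beta + \sigma^2_\epsilon}. The object
#' stores the factor form only (never a p x p matrix); matrix-vector
#' products, solves, quadratic forms and the log-determinant go through the
#' Woodbury identity and the matrix determinant lemma with a core of size
#' r + r_k (+1 with the outcome).
#'
#' @param params A [poplsda_params()] object.
#' @param k Dataset id (name or index), or `"pooled"` for the joint part
#'   only with the average residual variance.
#' @param include_y Include the outcome row/column (covariance of (x, y))
#'   rather than of x alone.
#' @return An object of class `poplsda_cov` supporting [cov_matvec()],
#'   [cov_solve()], [cov_quad()], [cov_logdet()] and `as.matrix()` (dense
#'   assembly, intended for small p).
#' @export
implied_covariance <- function(params, k, include_y = FALSE) {
  validate_params(params)
  id <- resolve_dataset(params, k)
  ld <- dataset_loadings(params, id)
  L <- ld$A
  cvec <- NULL
  d <- rep(ld$sigma2_e, nrow(L))
  if (include_y) {
    cvec <- c(params$beta, rep(0, ncol(L) - length(params$beta)))
    L <- rbind(L, cvec)
    d <- c(d, params$sigma2_eps)
  }
  B <- sweep(L, 2, sqrt(ld$sz), "*")             # (p[+1]) x q factor
  core <- diag(ncol(B)) + crossprod(B / sqrt(d)) # I + B' D^-1 B
  R <- chol(core)
  structure(
    list(B = B, d = d, chol_core = R, dim = nrow(B), q = ncol(B),
         dataset = id, include_y = include_y, params = params),
    class = "poplsda_cov"
  )
}

#' @export
print.poplsda_cov <- function(x, ...) {
  cat("<poplsda_cov> dim =", x$dim, ", core rank =", x$q,
      if (x$include_y) "(x, y)" else "(x)", "dataset:", x$dataset, "\n")
  invisible(x)
}

#' @rdname implied_covariance
#' @param cov A `poplsda_cov` object.
#' @param v Vector or matrix (columns are vectors) of matching dimension.
#' @export
cov_matvec <- function(cov, v) {
  v <- as.matrix(v)
  cov$B %*% crossprod(cov$B, v) + cov$d * v
}

#' @rdname implied_covariance
#' @export
cov_solve <- function(cov, v) {
  v <- as.matrix(v)
  vd <- v / cov$d
  t1 <- crossprod(cov$B, vd)                       # q x m
  t2 <- backsolve(cov$chol_core, backsolve(cov$chol_core, t1, transpose = TRUE))
  vd - (cov$B / cov$d) %*% t2
}

#' @rdname implied_covariance
#' @export
cov_quad <- function(cov, v) {
  v <- as.matrix(v)
  t1 <- backsolve(cov$chol_core, crossprod(cov$B, v / cov$d), transpose = TRUE)
  colSums(v^2 / cov$d) - colSums(t1^2)
}

#' @rdname implied_covariance
#' @export
cov_logdet <- function(cov) {
  sum(log(cov$d)) + 2 * sum(log(diag(cov$chol_core)))
}

#' @export
as.matrix.poplsda_cov <- function(x, ...) {
  tcrossprod(x$B) + diag(x$d, nrow = x$dim)
}

#' Dense covariance assembly (for small p)
#'
#' @inheritParams implied_covariance
#' @return A dense covariance matrix.
#' @export
dense_covariance <- function(params, k, include_y = FALSE) {
  as.matrix(implied_covariance(params, k, include_y = include_y))
}

#' Observed-data log-likelihood
#'
#' Sum over datasets and samples of the zero-mean Gaussian log-density of
#' (x, y) under the implied covariance, evaluated through the implicit
#' representation.
#'
#' @param params A [poplsda_params()].
#' @param stack A standardized [omics_stack()] whose dataset ids match the
#'   parameters.
#' @param y Named list of encoded outcome vectors (see [encode_labels()]);
#'   derived from the stack's groups when `NULL`.
#' @return Scalar log-likelihood.
#' @export
poplsda_loglik <- function(params, stack, y = NULL) {
  stopifnot(inherits(stack, "omics_stack"))
  if (is.null(y)) y <- encode_labels(stack)
  ll <- 0
  for (id in names(stack$datasets)) {
    d <- stack$datasets[[id]]
    if (ncol(d$values) != nrow(params$W)) stop("feature dimension mismatch")
    if (nrow(d$values) != length(y[[id]])) stop("outcome length mismatch")
    cv <- implied_covariance(params, id, include_y = TRUE)
    obs <- rbind(t(d$values), y[[id]])             # (p+1) x N
    n <- ncol(obs)
    ll <- ll - 0.5 * (n * (cv$dim * log(2 * pi) + cov_logdet(cv)) +
                        sum(cov_quad(cv, obs)))
  }
  ll
}

#' Posterior means of the joint latent components given x
#'
#' \eqn{E[u \mid x] = \Lambda_u W' \Sigma_x^{-1} x}, computed through the
#' implicit covariance (core of size r + r_k).
#'
#' @param params A [poplsda_params()].
#' @param x Numeric vector of length p or an N x p matrix.
#' @param k Dataset id, index, or `"pooled"`.
#' @return An N x r matrix of posterior means (a 1 x r matrix for a vector
#'   input).
#' @export
posterior_scores <- function(params, x, k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(params$W)) stop("x must have p columns")
  id <- resolve_dataset(params, k)
  cv <- implied_covariance(params, id, include_y = FALSE)
  sol <- cov_solve(cv, t(x))                       # p x N
  r <- ncol(params$W)
  sc <- t(crossprod(params$W, sol)) *
    matrix(params$sigma_u, nrow = ncol(sol), ncol = r, byrow = TRUE)
  colnames(sc) <- paste0("u", seq_len(r))
  rownames(sc) <- rownames(x)
  sc
}

#' Effect sizes of features on the outcome
#'
#' The per-feature effect size is the composition of joint loadings and the
#' latent regression, `W %*% beta`; its squared elements rank features.
#'
#' @param params A [poplsda_params()] or [poplsda()] fit.
#' @return Tibble with columns `feature`, `effect`, `effect_sq`.
#' @export
effect_sizes <- function(params) {
  if (inherits(params, "poplsda_fit")) params <- params$params
  eff <- drop(params$W %*% params$beta)
  feats <- rownames(params$W)
  if (is.null(feats)) feats <- paste0("f", seq_along(eff))
  tibble::tibble(feature = feats, effect = unname(eff), effect_sq = unname(eff)^2)
}

#' Variance decomposition per dataset
#'
#' With orthonormal loadings, the trace of each covariance part equals the
#' corresponding latent-variance sum, so the fractions of total variance are
#' `sum(sigma_u) / T` (joint), `sum(sigma_v_k) / T` (specific) and
#' `p * sigma2_e_k / T` (residual), with T their sum.
#'
#' @param params A [poplsda_params()] or fit.
#' @param k Optional dataset id or index; all datasets when `NULL`.
#' @return Tibble with columns `dataset`, `joint`, `specific`, `residual`.
#' @export
variance_explained <- function(params, k = NULL) {
  if (inherits(params, "poplsda_fit")) params <- params$params
  ids <- names(params$sigma2_e)
  if (!is.null(k)) ids <- resolve_dataset(params, k)
  p <- nrow(params$W)
  purrr::map_dfr(ids, function(id) {
    j <- sum(params$sigma_u)
    s <- sum(params$sigma_v[[id]])
    e <- p * unname(params$sigma2_e[[id]])
    tt <- j + s + e
    tibble::tibble(dataset = id, joint = j / tt, specific = s / tt, residual = e / tt)
  })
}

#' Eigenvalues of the row-wise concatenated stack for scree inspection
#'
#' Top eigenvalues of the sample covariance of all samples stacked row-wise,
#' computed from the N x N Gram matrix (memory-efficient for p >> N). Used
#' to choose the numbers of joint and specific components.
#'
#' @param stack A standardized [omics_stack()].
#' @param n_top Number of leading eigenvalues to return.
#' @return Non-negative, non-increasing numeric vector.
#' @export
scree_eigenvalues <- function(stack, n_top = 10) {
  stopifnot(inherits(stack, "omics_stack"))
  X <- do.call(rbind, lapply(stack$datasets, `[[`, "values"))
  n <- nrow(X)
  if (n_top > n) {
    warning("n_top exceeds the total number of samples (", n, "); truncated")
    n_top <- n
  }
  ev <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) / (n - 1)
  ev[seq_len(n_top)]
}
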
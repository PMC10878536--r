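#' POPLS-DA parameter set
#'
#' The generative model for dataset k (one sample; all variables zero-mean
#' Gaussian) is
#' \deqn{x = W u + P_k v_k + e_k, \qquad y = \beta' u + \epsilon,}
#' with joint latent u of dimension r shared across datasets (diagonal
#' covariance `sigma_u`), dataset-specific latent v_k of dimension r_k
#' (diagonal covariance `sigma_v[[k]]`), isotropic residual `sigma2_e[k]` on
#' x and residual variance `sigma2_eps` on the outcome. `W` and each
#' `P[[k]]` have orthonormal columns; `sigma_u` is sorted non-increasing.
#'
#' @param W p x r joint loading matrix, orthonormal columns; rownames are
#'   the feature IDs.
#' @param P Named list (per dataset) of p x r_k specific loading matrices
#'   with orthonormal columns; `NULL` entries mean r_k = 0.
#' @param beta Length-r regression coefficients of the outcome on u.
#' @param sigma_u Length-r positive joint latent variances, non-increasing.
#' @param sigma_v Named list of length-r_k positive specific latent variances.
#' @param sigma2_e Named positive per-dataset residual variance of x.
#' @param sigma2_eps Positive residual variance of the outcome.
#'
#' @return An object of class `poplsda_params`.
#' @export
poplsda_params <- function(W, P, beta, sigma_u, sigma_v, sigma2_e, sigma2_eps) {
  W <- as.matrix(W)
  r <- ncol(W)
  stopifnot(length(beta) == r, length(sigma_u) == r)
  if (is.null(names(sigma2_e))) stop("sigma2_e must be named by dataset")
  ids <- names(sigma2_e)
  if (is.null(P)) P <- stats::setNames(vector("list", length(ids)), ids)
  if (!all(ids %in% names(P))) stop("P must be named by dataset")
  if (!all(ids %in% names(sigma_v))) stop("sigma_v must be named by dataset")
  obj <- structure(
    list(W = W, P = P[ids], beta = as.numeric(beta),
         sigma_u = as.numeric(sigma_u), sigma_v = sigma_v[ids],
         sigma2_e = sigma2_e, sigma2_eps = sigma2_eps),
    class = "poplsda_params"
  )
  validate_params(obj)
  obj
}

validate_params <- function(p, tol = 1e-8) {
  W <- p$W
  if (max(abs(crossprod(W) - diag(ncol(W)))) > tol) {
    stop("W columns are not orthonormal")
  }
  for (id in names(p$P)) {
    Pk <- p$P[[id]]
    if (is.null(Pk)) next
    if (nrow(Pk) != nrow(W)) stop("P[['", id, "']] row count differs from W")
    if (ncol(Pk) && max(abs(crossprod(Pk) - diag(ncol(Pk)))) > tol) {
      stop("P[['", id, "']] columns are not orthonormal")
    }
    if (length(p$sigma_v[[id]]) != ncol(Pk)) stop("sigma_v length mismatch for '", id, "'")
  }
  if (any(p$sigma_u <= 0) || any(unlist(p$sigma_v) <= 0, na.rm = TRUE) ||
      any(p$sigma2_e <= 0) || p$sigma2_eps <= 0) {
    stop("all variance parameters must be positive")
  }
  if (is.unsorted(rev(p$sigma_u), strictly = FALSE)) {
    stop("sigma_u must be non-increasing")
  }
  invisible(p)
}

#' @export
print.poplsda_params <- function(x, ...) {
  cat("<poplsda_params> p =", nrow(x$W), ", r =", ncol(x$W),
      ", r_k = [", paste(vapply(x$P, function(m) if (is.null(m)) 0L else ncol(m),
                                integer(1)), collapse = ", "),
      "], K =", length(x$sigma2_e), "\n")
  invisible(x)
}

# dataset id -> canonical id, accepting index or name
resolve_dataset <- function(params, k) {
  ids <- names(params$sigma2_e)
  if (is.numeric(k)) {
    if (k < 1 || k > length(ids)) stop("dataset index out of range")
    return(ids[[k]])
  }
  if (identical(k, "pooled")) return("pooled")
  if (!k %in% ids) stop("unknown dataset id '", k, "'")
  k
}

# loading matrix [W P_k] and latent variance vector for a dataset
dataset_loadings <- function(params, id) {
  if (identical(id, "pooled")) {
    return(list(A = params$W, sz = params$sigma_u,
                sigma2_e = mean(params$sigma2_e), r = ncol(params$W)))
  }
  Pk <- params$P[[id]]
  A <- if (is.null(Pk) || ncol(Pk) == 0) params$W else cbind(params$W, Pk)
  sz <- c(params$sigma_u, params$sigma_v[[id]])
  list(A = A, sz = sz, sigma2_e = unname(params$sigma2_e[[id]]), r = ncol(params$W))
}
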
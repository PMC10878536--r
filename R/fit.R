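#' Fit the POPLS-DA model by memory-efficient maximum likelihood
#'
#' Expectation-maximization on the joint Gaussian of (x, y). The E-step
#' computes, per sample, posterior first and second moments of the stacked
#' latent vector (u, v_k) given (x, y) through a core linear solve of size
#' r + r_k + 1; no p x p matrix is ever formed. The M-step maximizes the
#' expected complete-data log-likelihood in closed form, solving for W
#' (shared) and all P_k jointly from the coupled normal equations, then
#' updating beta and all variances (conditional-maximization order, which
#' keeps the ascent property). After every iteration W and each P_k are
#' re-orthonormalized by a thin SVD with the mixing absorbed into
#' `sigma_u` / `sigma_v` and `beta` — a likelihood-invariant
#' reparameterization — and each column's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' Estimation is run from `n_starts` seeded initializations (one spectral,
#' from a Gram-matrix low-rank decomposition of the stacked data; the rest
#' random) and the best final likelihood is kept.
#'
#' @param stack A standardized [omics_stack()] (see [standardize_stack()]).
#' @param r Number of joint components (default 2).
#' @param r_k Number(s) of dataset-specific components; a scalar is recycled
#'   across datasets (default 2). Zero disables the specific part.
#' @param y Optional named list of encoded outcomes; derived from the
#'   stack's groups when `NULL`.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below `tol` (default 1e-6) or after
#'   `max_iter` iterations (default 1000).
#' @param n_starts Number of initializations (default 5).
#' @param seed Integer seed driving all randomness of the fit.
#' @param verbose Print per-start progress.
#'
#' @return An object of class `poplsda_fit` with elements `params`
#'   ([poplsda_params()]), `loglik` and `loglik_trace`, `scores` (per-dataset
#'   posterior means of u given x only), `effect_sizes` and `varexpl`
#'   tibbles, `converged`, `n_iter`, `seed`, `start_logliks`.
#' @export
poplsda <- function(stack, r = 2, r_k = 2, y = NULL, max_iter = 1000,
                    tol = 1e-6, n_starts = 5, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(stack, "omics_stack"), r >= 1)
  ids <- names(stack$datasets)
  K <- length(ids)
  if (length(r_k) == 1L) r_k <- rep(r_k, K)
  if (length(r_k) != K) stop("r_k must have one entry per dataset")
  r_k <- stats::setNames(as.integer(r_k), ids)
  if (is.null(y)) y <- encode_labels(stack)
  y <- y[ids]
  X <- lapply(stack$datasets, `[[`, "values")
  n_k <- vapply(X, nrow, integer(1))
  if (any(n_k < 2L)) stop("every dataset needs at least 2 samples")
  if (!all(vapply(X, function(m) all(is.finite(m)), logical(1)))) {
    stop("non-finite values in the stack")
  }
  p <- length(stack$feature_ids)
  if (any(r + max(r_k) + 1 > n_k)) {
    warning("r + max(r_k) + 1 exceeds a dataset's sample size; ",
            "the fit may be weakly identified")
  }
  if (is.null(seed)) seed <- 1L
  start_seeds <- make_substream_seeds(seed, n_starts)

  best <- NULL
  start_logliks <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    init <- em_initialize(X, y, r, r_k, p, ids,
                          seed = start_seeds[s], spectral = (s == 1L))
    run <- em_run(init, X, y, r, r_k, n_k, p, ids, max_iter, tol)
    start_logliks[s] <- run$loglik
    if (verbose) {
      message(sprintf("start %d: loglik %.6f after %d iterations%s", s,
                      run$loglik, run$n_iter,
                      if (run$converged) "" else " (not converged)"))
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  params <- best$params
  rownames(params$W) <- stack$feature_ids
  scores <- lapply(ids, function(id) posterior_scores(params, X[[id]], id))
  names(scores) <- ids
  structure(
    list(params = params, loglik = best$loglik, loglik_trace = best$trace,
         scores = scores, effect_sizes = effect_sizes(params),
         varexpl = variance_explained(params), converged = best$converged,
         n_iter = best$n_iter, seed = seed, start_logliks = start_logliks,
         r = r, r_k = r_k, dataset_ids = ids, feature_ids = stack$feature_ids),
    class = "poplsda_fit"
  )
}

#' @export
print.poplsda_fit <- function(x, ...) {
  cat("<poplsda_fit> p =", length(x$feature_ids), ", r =", x$r,
      ", r_k = [", paste(x$r_k, collapse = ", "), "]\n")
  cat("  log-likelihood:", format(x$loglik), "after", x$n_iter, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  ve <- x$varexpl
  for (i in seq_len(nrow(ve))) {
    cat(sprintf("  %s: %.1f%% joint, %.1f%% specific, %.1f%% residual\n",
                ve$dataset[i], 100 * ve$joint[i], 100 * ve$specific[i],
                100 * ve$residual[i]))
  }
  invisible(x)
}

# deterministic substream seeds (kept below 2^31)
make_substream_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

em_initialize <- function(X, y, r, r_k, p, ids, seed, spectral) {
  set.seed(seed)
  K <- length(ids)
  n_tot <- sum(vapply(X, nrow, integer(1)))
  if (spectral) {
    Xall <- do.call(rbind, X)
    dec <- gram_top_vectors(Xall, r)
    W0 <- dec$V
    su0 <- pmax(dec$values / max(1, n_tot - 1), 1e-2)
    P0 <- list(); sv0 <- list()
    for (id in ids) {
      if (r_k[[id]] == 0L) { P0[id] <- list(NULL); sv0[[id]] <- numeric(0); next }
      res <- X[[id]] - (X[[id]] %*% W0) %*% t(W0)
      dk <- gram_top_vectors(res, r_k[[id]])
      P0[[id]] <- dk$V
      sv0[[id]] <- pmax(dk$values / max(1, nrow(res) - 1), 1e-2)
    }
    sig_e0 <- vapply(X, function(m) max(mean(m^2) * 0.5, 1e-3), numeric(1))
    sc <- do.call(rbind, lapply(X, function(m) m %*% W0))
    yy <- unlist(y, use.names = FALSE)
    beta0 <- drop(solve(crossprod(sc) + 1e-8 * diag(r), crossprod(sc, yy)))
  } else {
    W0 <- random_orthonormal(p, r, seed = seed + 1L)
    su0 <- sort(stats::rexp(r) + 0.5, decreasing = TRUE)
    P0 <- list(); sv0 <- list()
    for (id in ids) {
      if (r_k[[id]] == 0L) { P0[id] <- list(NULL); sv0[[id]] <- numeric(0); next }
      P0[[id]] <- random_orthonormal(p, r_k[[id]], seed = seed + 1L + match(id, ids))
      sv0[[id]] <- sort(stats::rexp(r_k[[id]]) + 0.5, decreasing = TRUE)
    }
    sig_e0 <- stats::setNames(rep(0.5, K), ids)
    beta0 <- stats::rnorm(r)
  }
  su0 <- sort(su0, decreasing = TRUE)
  poplsda_params(W = W0, P = P0, beta = beta0, sigma_u = su0, sigma_v = sv0,
                 sigma2_e = stats::setNames(sig_e0, ids),
                 sigma2_eps = max(stats::var(unlist(y, use.names = FALSE)), 1e-2))
}

# top right singular vectors of X (n x p) via its n x n Gram matrix
gram_top_vectors <- function(X, r) {
  n <- nrow(X)
  eg <- eigen(tcrossprod(X), symmetric = TRUE)
  r_eff <- min(r, n)
  vals <- pmax(eg$values[seq_len(r_eff)], 1e-12)
  V <- crossprod(X, eg$vectors[, seq_len(r_eff), drop = FALSE]) %*%
    diag(1 / sqrt(vals), r_eff)
  if (r_eff < r) {  # pad with random directions
    extra <- matrix(stats::rnorm(nrow(V) * (r - r_eff)), ncol = r - r_eff)
    V <- cbind(V, extra)
    vals <- c(vals, rep(min(vals), r - r_eff))
  }
  # re-orthonormalize against numerical drift, keeping column directions
  Q <- qr.Q(qr(V))
  Q <- sweep(Q, 2, sign(colSums(Q * V) + (colSums(Q * V) == 0)), "*")
  list(V = Q, values = vals)
}

em_run <- function(params, X, y, r, r_k, n_k, p, ids, max_iter, tol) {
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  n_tot <- sum(n_k)
  sumy2 <- sum(unlist(y, use.names = FALSE)^2)
  floor_var <- 1e-12
  Xt <- lapply(X, t)                       # p x N, reused every iteration
  sumx2_k <- vapply(X, function(m) sum(m^2), numeric(1))
  obs <- lapply(ids, function(id) rbind(Xt[[id]], y[[id]]))
  names(obs) <- ids

  for (iter in seq_len(max_iter)) {
    # ---- E-step: per-dataset posterior moments of z = (u, v_k) | (x, y)
    est <- lapply(ids, function(id) {
      ld <- dataset_loadings(params, id)
      q <- ncol(ld$A)
      cvec <- c(params$beta, rep(0, q - r))
      M <- diag(1 / ld$sz, q) + crossprod(ld$A) / ld$sigma2_e +
        tcrossprod(cvec) / params$sigma2_eps
      V <- chol2inv(chol(M))
      rhs <- crossprod(ld$A, Xt[[id]]) / ld$sigma2_e +
        outer(cvec, y[[id]]) / params$sigma2_eps
      Mean <- V %*% rhs                                    # q x N
      S_zz <- tcrossprod(Mean) + n_k[[id]] * V
      S_xz <- tcrossprod(Xt[[id]], Mean)                   # p x q
      S_zy <- drop(Mean %*% y[[id]])
      list(S_zz = S_zz, S_xz = S_xz, S_zy = S_zy, sumx2 = sumx2_k[[id]])
    })
    names(est) <- ids

    # ---- M-step: W and all P_k from the coupled normal equations
    iu <- seq_len(r)
    lhs_W <- matrix(0, p, r); rhs_W <- matrix(0, r, r)
    Hk <- list()
    for (id in ids) {
      e <- est[[id]]
      w_k <- 1 / unname(params$sigma2_e[[id]])
      if (r_k[[id]] > 0L) {
        iv <- r + seq_len(r_k[[id]])
        Svv <- e$S_zz[iv, iv, drop = FALSE]
        H <- solve(Svv + 1e-10 * diag(nrow(Svv)))
        Hk[[id]] <- H
        Svu <- e$S_zz[iv, iu, drop = FALSE]
        lhs_W <- lhs_W + w_k * (e$S_xz[, iu, drop = FALSE] -
                                  e$S_xz[, iv, drop = FALSE] %*% H %*% Svu)
        rhs_W <- rhs_W + w_k * (e$S_zz[iu, iu, drop = FALSE] -
                                  t(Svu) %*% H %*% Svu)
      } else {
        lhs_W <- lhs_W + w_k * e$S_xz[, iu, drop = FALSE]
        rhs_W <- rhs_W + w_k * e$S_zz[iu, iu, drop = FALSE]
      }
    }
    W_new <- lhs_W %*% solve(rhs_W + 1e-10 * diag(r))
    P_new <- list()
    for (id in ids) {
      if (r_k[[id]] == 0L) { P_new[id] <- list(NULL); next }
      iv <- r + seq_len(r_k[[id]])
      e <- est[[id]]
      P_new[[id]] <- (e$S_xz[, iv, drop = FALSE] -
                        W_new %*% e$S_zz[iu, iv, drop = FALSE]) %*% Hk[[id]]
    }

    # ---- beta and outcome residual variance
    Suu_tot <- Reduce(`+`, lapply(est, function(e) e$S_zz[iu, iu, drop = FALSE]))
    Suy_tot <- Reduce(`+`, lapply(est, function(e) e$S_zy[iu]))
    beta_new <- drop(solve(Suu_tot + 1e-10 * diag(r), Suy_tot))
    sig_eps_new <- max((sumy2 - 2 * sum(beta_new * Suy_tot) +
                          drop(t(beta_new) %*% Suu_tot %*% beta_new)) / n_tot,
                       floor_var)

    # ---- residual and latent variances
    sig_e_new <- numeric(0)
    sv_new <- list()
    for (id in ids) {
      e <- est[[id]]
      A_new <- if (r_k[[id]] > 0L) cbind(W_new, P_new[[id]]) else W_new
      rss <- e$sumx2 - 2 * sum(A_new * e$S_xz) +
        sum(crossprod(A_new) * e$S_zz)
      sig_e_new[id] <- max(rss / (n_k[[id]] * p), floor_var)
      sv_new[[id]] <- if (r_k[[id]] > 0L) {
        iv <- r + seq_len(r_k[[id]])
        pmax(diag(e$S_zz)[iv] / n_k[[id]], floor_var)
      } else numeric(0)
    }
    su_new <- pmax(diag(Suu_tot) / n_tot, floor_var)

    params <- canonicalize_params(W_new, P_new, beta_new, su_new, sv_new,
                                  sig_e_new, sig_eps_new, ids,
                                  validate = FALSE)

    # ---- convergence on the observed-data log-likelihood
    ll <- loglik_lean(params, obs, ids, r)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / max(1, abs(ll_old)) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  validate_params(params)
  list(params = params, loglik = ll_old, trace = trace,
       converged = converged, n_iter = length(trace))
}

# observed-data log-likelihood from precomputed (p+1) x N observation
# matrices, via the Woodbury identity on the (r + r_k + 1) core
loglik_lean <- function(params, obs, ids, r) {
  ll <- 0
  for (id in ids) {
    ld <- dataset_loadings(params, id)
    q <- ncol(ld$A)
    cvec <- c(params$beta, rep(0, q - r))
    B <- rbind(ld$A, cvec) * rep(sqrt(ld$sz), each = nrow(ld$A) + 1L)
    d <- c(rep(ld$sigma2_e, nrow(ld$A)), params$sigma2_eps)
    R <- chol(diag(q) + crossprod(B / sqrt(d)))
    w <- obs[[id]]
    n <- ncol(w)
    t1 <- backsolve(R, crossprod(B, w / d), transpose = TRUE)
    quad <- colSums(w^2 / d) - colSums(t1^2)
    logdet <- sum(log(d)) + 2 * sum(log(diag(R)))
    ll <- ll - 0.5 * (n * (nrow(w) * log(2 * pi) + logdet) + sum(quad))
  }
  ll
}

# Likelihood-invariant canonical form: thin SVD of W diag(sqrt(su)) (resp.
# P_k diag(sqrt(sv))) re-orthonormalizes the loadings, absorbs the mixing
# into the latent variances (and beta for the joint part), sorts variances
# non-increasing, and fixes column signs.
canonicalize_params <- function(W, P, beta, su, sv, sig_e, sig_eps, ids,
                                validate = TRUE) {
  r <- ncol(W)
  sW <- svd(W * rep(sqrt(su), each = nrow(W)), nu = r, nv = r)
  d <- pmax(sW$d, 1e-12)
  W_c <- sW$u
  su_c <- d^2
  beta_c <- drop(crossprod(sW$v, sqrt(su) * beta)) / d
  # column sign: largest-magnitude loading positive
  for (j in seq_len(r)) {
    m <- which.max(abs(W_c[, j]))
    if (W_c[m, j] < 0) { W_c[, j] <- -W_c[, j]; beta_c[j] <- -beta_c[j] }
  }
  P_c <- list(); sv_c <- list()
  for (id in ids) {
    if (is.null(P[[id]]) || ncol(P[[id]]) == 0L) {
      P_c[id] <- list(NULL); sv_c[[id]] <- numeric(0); next
    }
    sP <- svd(P[[id]] * rep(sqrt(sv[[id]]), each = nrow(P[[id]])))
    dk <- pmax(sP$d, 1e-12)
    Pk <- sP$u
    for (j in seq_len(ncol(Pk))) {
      m <- which.max(abs(Pk[, j]))
      if (Pk[m, j] < 0) Pk[, j] <- -Pk[, j]
    }
    P_c[[id]] <- Pk
    sv_c[[id]] <- dk^2
  }
  out <- structure(
    list(W = W_c, P = P_c[ids], beta = beta_c, sigma_u = su_c,
         sigma_v = sv_c[ids], sigma2_e = stats::setNames(sig_e, ids),
         sigma2_eps = sig_eps),
    class = "poplsda_params"
  )
  if (validate) validate_params(out)
  out
}
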
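test_that("scalar model reproduces closed-form covariance entries", {
  pr <- poplsda_params(
    W = matrix(1, 1, 1, dimnames = list("g1", NULL)),
    P = list(d1 = NULL), beta = 1, sigma_u = 1,
    sigma_v = list(d1 = numeric(0)), sigma2_e = c(d1 = 1), sigma2_eps = 1
  )
  S <- dense_covariance(pr, "d1", include_y = TRUE)
  expect_equal(S, matrix(c(2, 1, 1, 2), 2), ignore_attr = TRUE)
})

test_that("beta = 0 makes x and y independent", {
  pr <- toy_params(p = 4, r = 2, r_k = c(1, 1), seed = 3)
  pr$beta <- c(0, 0)
  S <- dense_covariance(pr, "omics1", include_y = TRUE)
  expect_equal(unname(S[5, 1:4]), rep(0, 4))
  expect_equal(S[5, 5], pr$sigma2_eps)
})

test_that("implicit covariance operations match dense assembly", {
  for (seed in 1:6) {
    pr <- toy_params(p = 6, r = 2, r_k = c(2, 1), seed = seed)
    for (ky in c(TRUE, FALSE)) {
      cv <- implied_covariance(pr, "omics1", include_y = ky)
      S <- dense_covariance(pr, "omics1", include_y = ky)
      d <- nrow(S)
      set.seed(seed + 100)
      v <- matrix(rnorm(d * 3), d, 3)
      expect_equal(cov_matvec(cv, v), S %*% v, tolerance = 1e-8)
      expect_equal(cov_solve(cv, v), solve(S, v), tolerance = 1e-8)
      expect_equal(cov_quad(cv, v), diag(t(v) %*% solve(S, v)),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(cov_logdet(cv), determinant(S)$modulus[1],
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("log-likelihood matches the closed form and a dense oracle", {
  # single sample at the origin, scalar model: -log(2*pi) - 0.5*log(3)
  pr <- poplsda_params(
    W = matrix(1, 1, 1, dimnames = list("g1", NULL)),
    P = list(d1 = NULL), beta = 1, sigma_u = 1,
    sigma_v = list(d1 = numeric(0)), sigma2_e = c(d1 = 1), sigma2_eps = 1
  )
  d <- omics_dataset(matrix(0, 2, 1), "d1", feature_ids = "g1",
                     groups = c("case", "control"))
  st <- omics_stack(list(d))
  y <- list(d1 = c(0, 0))
  expect_equal(poplsda_loglik(pr, st, y), 2 * (-log(2 * pi) - 0.5 * log(3)))

  # dense multivariate-normal oracle on K = 2, p = 8
  set.seed(5)
  pr2 <- toy_params(p = 8, r = 2, r_k = c(2, 2), seed = 5)
  X1 <- matrix(rnorm(5 * 8), 5, 8); X2 <- matrix(rnorm(5 * 8), 5, 8)
  st2 <- omics_stack(list(
    toy_dataset(X1, "omics1", groups = c("case", "case", "control", "control", "case")),
    toy_dataset(X2, "omics2", groups = c("case", "control", "control", "case", "case"))
  ))
  y2 <- encode_labels(st2)
  oracle <- dense_mvn_loglik(rbind(t(X1), y2$omics1),
                             dense_covariance(pr2, "omics1", include_y = TRUE)) +
    dense_mvn_loglik(rbind(t(X2), y2$omics2),
                     dense_covariance(pr2, "omics2", include_y = TRUE))
  expect_equal(poplsda_loglik(pr2, st2, y2), oracle, tolerance = 1e-8)

  # additivity: duplicating every sample doubles the log-likelihood
  st2dup <- omics_stack(lapply(st2$datasets, function(d) {
    omics_dataset(rbind(d$values, d$values), d$dataset_id,
                  c(d$sample_ids, paste0(d$sample_ids, "b")),
                  d$feature_ids, c(d$groups, d$groups))
  }))
  y2dup <- lapply(y2, rep, times = 2)
  expect_equal(poplsda_loglik(pr2, st2dup, y2dup),
               2 * poplsda_loglik(pr2, st2, y2), tolerance = 1e-10)
})

test_that("posterior scores follow the conditional-mean formula", {
  pr <- poplsda_params(
    W = matrix(1, 1, 1, dimnames = list("g1", NULL)),
    P = list(d1 = NULL), beta = 1, sigma_u = 1,
    sigma_v = list(d1 = numeric(0)), sigma2_e = c(d1 = 1), sigma2_eps = 1
  )
  expect_equal(drop(posterior_scores(pr, 2, "d1")), 1,
               ignore_attr = TRUE)   # 1*1*(1/2)*2
  expect_equal(drop(posterior_scores(pr, 0, "d1")), 0, ignore_attr = TRUE)

  pr2 <- toy_params(p = 6, r = 2, r_k = c(2, 1), seed = 9)
  set.seed(9)
  X <- matrix(rnorm(4 * 6), 4, 6)
  sc <- posterior_scores(pr2, X, "omics1")
  Sx <- dense_covariance(pr2, "omics1", include_y = FALSE)
  oracle <- t(diag(pr2$sigma_u) %*% t(pr2$W) %*% solve(Sx, t(X)))
  expect_equal(sc, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("prediction is linear with the control tie rule", {
  pr <- poplsda_params(
    W = matrix(1, 1, 1, dimnames = list("g1", NULL)),
    P = list(d1 = NULL), beta = 1, sigma_u = 1,
    sigma_v = list(d1 = numeric(0)), sigma2_e = c(d1 = 1), sigma2_eps = 1
  )
  pred <- predict(pr, matrix(2, 1, 1), dataset = "d1")
  expect_equal(pred$score, 1)
  expect_identical(pred$class, "case")
  tie <- predict(pr, matrix(0, 1, 1), dataset = "d1")
  expect_equal(tie$score, 0)
  expect_identical(tie$class, "control")
  neg <- predict(pr, matrix(-2, 1, 1), dataset = "d1")
  expect_equal(neg$score, -pred$score)
  expect_identical(neg$class, "control")
})

test_that("effect sizes obey the rank-1 and orthonormality identities", {
  pr <- toy_params(p = 7, r = 2, r_k = c(1, 1), seed = 2)
  es <- effect_sizes(pr)
  expect_equal(es$effect, drop(pr$W %*% pr$beta), ignore_attr = TRUE)
  expect_equal(sum(es$effect_sq), sum(pr$beta^2), tolerance = 1e-10)
  pr$beta <- c(0, 0)
  expect_equal(effect_sizes(pr)$effect, rep(0, 7))
  # rank-1: effects are b * w
  w <- random_orthonormal(5, 1, seed = 4)
  rownames(w) <- paste0("g", 1:5)
  pr1 <- poplsda_params(W = w, P = list(d1 = NULL), beta = 3, sigma_u = 1,
                        sigma_v = list(d1 = numeric(0)),
                        sigma2_e = c(d1 = 1), sigma2_eps = 1)
  expect_equal(effect_sizes(pr1)$effect, 3 * drop(w), ignore_attr = TRUE)
})

test_that("variance fractions match arithmetic and dense trace ratios", {
  W <- random_orthonormal(10, 2, seed = 6); rownames(W) <- paste0("g", 1:10)
  P1 <- random_orthonormal(10, 1, seed = 7)
  pr <- poplsda_params(W = W, P = list(d1 = P1), beta = c(1, 1),
                       sigma_u = c(2, 1), sigma_v = list(d1 = 1),
                       sigma2_e = c(d1 = 0.1), sigma2_eps = 1)
  ve <- variance_explained(pr, "d1")
  expect_equal(ve$joint, 3 / 5)
  expect_equal(ve$joint + ve$specific + ve$residual, 1)
  # dense trace oracle
  joint_tr <- sum(diag(W %*% diag(c(2, 1)) %*% t(W)))
  spec_tr <- sum(diag(P1 %*% t(P1)))
  res_tr <- 10 * 0.1
  expect_equal(ve$joint, joint_tr / (joint_tr + spec_tr + res_tr),
               tolerance = 1e-10)
  # no specific part, vanishing residual -> joint fraction tends to 1
  pr2 <- poplsda_params(W = W, P = list(d1 = NULL), beta = c(1, 1),
                        sigma_u = c(2, 1), sigma_v = list(d1 = numeric(0)),
                        sigma2_e = c(d1 = 1e-9), sigma2_eps = 1)
  expect_gt(variance_explained(pr2, "d1")$joint, 0.999)
})

test_that("scree eigenvalues are computed from the Gram matrix correctly", {
  # all rows identical and nonzero -> exactly one positive eigenvalue
  m <- matrix(rep(c(1, 2, 3, 4), each = 4), 4, 4)
  d <- omics_dataset(m, "d", feature_ids = paste0("g", 1:4),
                     sample_ids = paste0("s", 1:4),
                     groups = c("case", "control", "case", "control"))
  ev <- scree_eigenvalues(omics_stack(list(d)), n_top = 4)
  expect_gt(ev[1], 0)
  expect_equal(ev[-1], rep(0, 3), tolerance = 1e-10)

  # designed orthogonal toy with known sample-covariance spectrum
  u1 <- c(1, 1, 1, 1) / 2; u2 <- c(1, -1, 1, -1) / 2
  X <- sqrt(3) * outer(c(1, -1, 1, -1), u1) + sqrt(3) * outer(c(1, 1, -1, -1), u2)
  # crossprod(X)/(n-1) has eigenvalues {4, 4, 0, 0}: check against dense eigen
  dd <- omics_dataset(X, "d", feature_ids = paste0("g", 1:4),
                      sample_ids = paste0("s", 1:4),
                      groups = c("case", "control", "case", "control"))
  ev2 <- scree_eigenvalues(omics_stack(list(dd)), n_top = 4)
  dense <- sort(eigen(crossprod(X) / 3, only.values = TRUE)$values,
                decreasing = TRUE)
  expect_equal(ev2, dense, tolerance = 1e-10)

  # standardized stack: eigenvalue sum bounded by the feature count
  st <- standardize_stack(toy_stack(p = 6))
  evs <- scree_eigenvalues(st, n_top = 14)
  expect_true(all(diff(evs) <= 1e-12))
  expect_lte(sum(evs), 6 + 1e-8)
  expect_warning(scree_eigenvalues(st, n_top = 99), "truncated")
})
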
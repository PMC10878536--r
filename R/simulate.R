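#' Random matrix with orthonormal columns
#'
#' QR orthonormalization of a seeded Gaussian matrix, with a deterministic
#' sign convention (positive diagonal of R).
#'
#' @param p,r Dimensions, `r <= p`.
#' @param seed Optional integer seed.
#' @return A p x r matrix Q with `t(Q) %*% Q` the identity.
#' @export
random_orthonormal <- function(p, r, seed = NULL) {
  if (r > p) stop("r must not exceed p")
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(p * r), nrow = p, ncol = r)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  sweep(Q, 2, sign(diag(qr.R(qrd))), "*")
}

#' Simulation configuration for the generative model
#'
#' Bundles every parameter of the generative model plus the sparsity of the
#' joint loadings: only `support_size` designated features (the first
#' `support_size` after a seeded shuffle) carry nonzero joint loadings, so
#' ground-truth relevant features are known.
#'
#' @param p Number of shared features.
#' @param n_k Integer vector of per-dataset sample sizes (length K).
#' @param r,r_k Numbers of joint / specific components (scalar `r_k`
#'   recycled).
#' @param sigma_u Joint latent variances (length r, non-increasing).
#' @param sigma_v List (or single vector recycled) of specific latent
#'   variances per dataset.
#' @param sigma2_e Per-dataset residual variance (scalar recycled).
#' @param sigma2_eps Outcome residual variance.
#' @param beta Latent regression coefficients (length r).
#' @param support_size Number of features with nonzero joint loadings
#'   (`NULL` = all p).
#' @param margin Group-separation margin in standard deviations of the
#'   continuous outcome: samples with `|y*| < margin * sd(y*)` are redrawn,
#'   emulating two distinct experimental conditions rather than a
#'   threshold-of-Gaussian split. 0 (default) disables the rejection.
#' @param dataset_ids Names for the K datasets.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p = 100, n_k = c(10, 10), r = 2, r_k = 2,
                       sigma_u = c(3, 2), sigma_v = c(2, 1),
                       sigma2_e = 1, sigma2_eps = 0.05,
                       beta = c(1.5, 0.8), support_size = NULL, margin = 0,
                       dataset_ids = paste0("omics", seq_along(n_k)),
                       seed = 1) {
  K <- length(n_k)
  if (length(r_k) == 1L) r_k <- rep(r_k, K)
  if (!is.list(sigma_v)) sigma_v <- rep(list(sigma_v), K)
  if (length(sigma2_e) == 1L) sigma2_e <- rep(sigma2_e, K)
  stopifnot(length(sigma_u) == r, length(beta) == r, length(r_k) == K,
            length(sigma_v) == K, length(sigma2_e) == K,
            all(n_k > 0), all(sigma_u > 0), sigma2_eps > 0, all(sigma2_e > 0))
  for (k in seq_len(K)) stopifnot(length(sigma_v[[k]]) == r_k[k])
  if (!is.null(support_size)) stopifnot(support_size >= r, support_size <= p)
  stopifnot(margin >= 0)
  structure(
    list(p = p, K = K, n_k = n_k, r = r, r_k = r_k,
         sigma_u = sort(sigma_u, decreasing = TRUE), sigma_v = sigma_v,
         sigma2_e = sigma2_e, sigma2_eps = sigma2_eps, beta = beta,
         support_size = support_size, margin = margin,
         dataset_ids = dataset_ids, seed = seed),
    class = "sim_config"
  )
}

#' Two-omics configuration mirroring a small cell-line study
#'
#' A preset with K = 2 layers on disjoint samples: a 3 + 3 case/control
#' transcriptome layer and an 18-sample proteome layer, two joint and two
#' specific components, and latent variances sized so that roughly a fifth
#' of each layer's variance is joint and a quarter dataset-specific. The
#' feature count defaults to 500 (configurable down or up from the
#' thousands a real study would have, for speed). Group labels threshold
#' the continuous latent outcome and are redrawn below a one-standard-
#' deviation margin, emulating two clearly distinct experimental
#' conditions.
#'
#' @param p Number of shared features.
#' @param support_size Number of truly relevant features (default 12% of p).
#' @param margin Group-separation margin (see [sim_config()]; default 1).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
luhmes_config <- function(p = 500, support_size = max(4L, round(0.12 * p)),
                          margin = 1, seed = 1) {
  su_tot <- 0.21 / 0.52 * p   # joint : residual = 21 : 52 with sigma2_e = 1
  sv_tot <- 0.27 / 0.52 * p
  sim_config(
    p = p, n_k = c(6, 18), r = 2, r_k = 2,
    sigma_u = su_tot * c(0.6, 0.4), sigma_v = sv_tot * c(0.6, 0.4),
    sigma2_e = 1, sigma2_eps = 0.05, beta = c(0.5, 0.25),
    support_size = support_size, margin = margin,
    dataset_ids = c("transcriptomics", "proteomics"), seed = seed
  )
}

#' Simulate a multi-omics stack from the generative model
#'
#' Draws latent variables and noise as independent zero-mean Gaussians with
#' the configured variances, assembles `x = u W' + v P_k' + e` per dataset,
#' forms the continuous outcome `y* = u beta + eps` and thresholds it at
#' zero into case (`y* > 0`) / control groups. Joint loadings are supported
#' on `support_size` designated features. Each dataset uses its own seeded
#' substream; a dataset whose labels come out degenerate (single class) is
#' redrawn up to 100 times.
#'
#' @param config A [sim_config()].
#' @return A list with `stack` (an [omics_stack()]), `y_star` (named list of
#'   continuous outcomes), `params` (true [poplsda_params()]) and `support`
#'   (character vector of truly relevant feature IDs).
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  feature_ids <- sprintf("g%04d", seq_len(cf$p))
  support_idx <- if (is.null(cf$support_size)) seq_len(cf$p) else
    sort(sample.int(cf$p, cf$support_size))
  W <- matrix(0, cf$p, cf$r)
  W[support_idx, ] <- random_orthonormal(length(support_idx), cf$r)
  rownames(W) <- feature_ids
  P <- list(); sv <- list()
  dataset_seeds <- make_substream_seeds(cf$seed, cf$K)
  for (k in seq_len(cf$K)) {
    id <- cf$dataset_ids[k]
    if (cf$r_k[k] > 0L) {
      P[[id]] <- random_orthonormal(cf$p, cf$r_k[k], seed = dataset_seeds[k])
    } else P[id] <- list(NULL)
    sv[[id]] <- cf$sigma_v[[k]]
  }
  params <- poplsda_params(
    W = W, P = P, beta = cf$beta, sigma_u = cf$sigma_u, sigma_v = sv,
    sigma2_e = stats::setNames(cf$sigma2_e, cf$dataset_ids),
    sigma2_eps = cf$sigma2_eps
  )

  datasets <- list(); y_star <- list()
  for (k in seq_len(cf$K)) {
    id <- cf$dataset_ids[k]
    n <- cf$n_k[k]
    set.seed(dataset_seeds[k] %% .Machine$integer.max)
    sd_y <- sqrt(sum(cf$beta^2 * cf$sigma_u) + cf$sigma2_eps)
    draw <- function(n) {
      u <- matrix(stats::rnorm(n * cf$r), n) %*% diag(sqrt(cf$sigma_u), cf$r)
      v <- if (cf$r_k[k] > 0L) {
        matrix(stats::rnorm(n * cf$r_k[k]), n) %*%
          diag(sqrt(cf$sigma_v[[k]]), cf$r_k[k])
      } else NULL
      e <- matrix(stats::rnorm(n * cf$p, sd = sqrt(cf$sigma2_e[k])), n)
      x <- u %*% t(W) + e
      if (!is.null(v)) x <- x + v %*% t(P[[id]])
      ys <- drop(u %*% cf$beta) + stats::rnorm(n, sd = sqrt(cf$sigma2_eps))
      list(x = x, ys = ys)
    }
    for (attempt in seq_len(100L)) {
      d <- draw(n)
      x <- d$x; ys <- d$ys
      if (cf$margin > 0) {  # per-sample rejection below the margin
        for (redraw in seq_len(100L)) {
          low <- abs(ys) < cf$margin * sd_y
          if (!any(low)) break
          dd <- draw(sum(low))
          x[low, ] <- dd$x
          ys[low] <- dd$ys
        }
      }
      grp <- ifelse(ys > 0, "case", "control")
      if (length(unique(grp)) == 2L) break
      if (attempt == 100L) stop("degenerate groups in dataset '", id,
                                "' after 100 redraws")
    }
    colnames(x) <- feature_ids
    rownames(x) <- sprintf("%s_s%02d", id, seq_len(n))
    datasets[[id]] <- omics_dataset(x, id, groups = grp)
    y_star[[id]] <- ys
  }
  list(stack = omics_stack(datasets), y_star = y_star, params = params,
       support = feature_ids[support_idx])
}

#' Recovery metrics against simulation ground truth
#'
#' @param true_params,est_params [poplsda_params()] objects of matching
#'   dimension.
#' @param true_support Character vector of truly relevant features.
#' @param selected Character vector of selected features.
#' @return A tibble with `max_angle_deg` and `mean_angle_deg` (principal
#'   angles between the joint loading subspaces), `effect_cor` (Pearson
#'   correlation of |W beta| true vs estimated), `precision` and `recall`
#'   of the selection.
#' @export
recovery_metrics <- function(true_params, est_params, true_support = NULL,
                             selected = NULL) {
  ang <- principal_angles(true_params$W, est_params$W)
  eff_t <- abs(drop(true_params$W %*% true_params$beta))
  eff_e <- abs(drop(est_params$W %*% est_params$beta))
  cor_eff <- if (stats::sd(eff_t) > 0 && stats::sd(eff_e) > 0) {
    stats::cor(eff_t, eff_e)
  } else NA_real_
  prec <- rec <- NA_real_
  if (!is.null(true_support) && !is.null(selected)) {
    hit <- length(intersect(selected, true_support))
    prec <- hit / length(selected)
    rec <- hit / length(true_support)
  }
  tibble::tibble(max_angle_deg = max(ang) * 180 / pi,
                 mean_angle_deg = mean(ang) * 180 / pi,
                 effect_cor = cor_eff, precision = prec, recall = rec)
}

#' Principal angles between column spans of two orthonormal matrices
#'
#' @param A,B Matrices with orthonormal columns and equal row count. When
#'   the ranks differ the angles of the common dimension are returned with
#'   a warning.
#' @return Numeric vector of angles in radians, increasing.
#' @export
principal_angles <- function(A, B) {
  if (ncol(A) != ncol(B)) warning("rank mismatch; comparing the common dimension")
  s <- svd(crossprod(A, B))$d
  sort(acos(pmin(pmax(s, -1), 1)))
}

#' Random interaction-network and drug-target fixtures
#'
#' Erdos-Renyi style undirected gene graph plus a drug-target map assigning
#' each drug 1 to 3 uniformly chosen target genes. Deterministic given the
#' seed.
#'
#' @param n_genes,n_drugs Numbers of genes and drugs.
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `network` (a [ppi_network()]) and `drug_targets`
#'   (tibble with columns `drug`, `gene`).
#' @export
fixture_network <- function(n_genes = 20, n_drugs = 5, edge_prob = 0.2,
                            seed = 1) {
  stopifnot(edge_prob >= 0, edge_prob <= 1)
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  pairs <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  edges <- tibble::tibble(gene1 = pairs[1, keep], gene2 = pairs[2, keep],
                          score = 1)
  net <- ppi_network(edges, nodes = genes)
  drugs <- purrr::map_dfr(seq_len(n_drugs), function(i) {
    tibble::tibble(drug = sprintf("drug%02d", i),
                   gene = sample(genes, sample.int(3L, 1L)))
  })
  list(network = net, drug_targets = drugs)
}
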
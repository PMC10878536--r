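#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a fitted model
#'
#' One row per feature: joint loadings, effect size and its square.
#'
#' @param x A [poplsda()] fit.
#' @param ... Unused.
#' @return A tibble with `feature`, one `loading_*` column per joint
#'   component, `effect`, `effect_sq`.
#' @export
tidy.poplsda_fit <- function(x, ...) {
  W <- x$params$W
  colnames(W) <- paste0("loading_u", seq_len(ncol(W)))
  dplyr::bind_cols(tibble::tibble(feature = x$feature_ids),
                   tibble::as_tibble(W),
                   x$effect_sizes[, c("effect", "effect_sq")])
}

#' One-row model summary
#'
#' @param x A [poplsda()] fit.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, iteration count,
#'   convergence flag and the variance-explained fractions averaged over
#'   datasets.
#' @export
glance.poplsda_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    r = x$r, n_datasets = length(x$dataset_ids),
    joint_varexpl = mean(x$varexpl$joint),
    specific_varexpl = mean(x$varexpl$specific),
    residual_varexpl = mean(x$varexpl$residual)
  )
}

#' Sample scores of a fitted model as a tibble
#'
#' @param x A [poplsda()] fit.
#' @param data Optional [omics_stack()] to score instead of the training
#'   scores stored in the fit.
#' @param ... Unused.
#' @return Tibble with `dataset`, `sample_id`, per-component scores and the
#'   predicted `score`/`class`.
#' @export
augment.poplsda_fit <- function(x, data = NULL, ...) {
  if (!is.null(data)) {
    sc <- lapply(names(data$datasets), function(id) {
      posterior_scores(x$params, data$datasets[[id]]$values,
                       if (id %in% x$dataset_ids) id else "pooled")
    })
    names(sc) <- names(data$datasets)
    groups <- lapply(data$datasets, `[[`, "groups")
    samples <- lapply(data$datasets, `[[`, "sample_ids")
  } else {
    sc <- x$scores
    groups <- samples <- NULL
  }
  purrr::map_dfr(names(sc), function(id) {
    m <- sc[[id]]
    tb <- tibble::as_tibble(m)
    pred <- drop(m %*% x$params$beta)
    dplyr::bind_cols(
      tibble::tibble(
        dataset = id,
        sample_id = if (is.null(samples)) rownames(m) else samples[[id]]
      ),
      tb,
      tibble::tibble(score = unname(pred),
                     class = ifelse(pred > 0, "case", "control"))
    )
  })
}

#' @importFrom generics augment
#' @export
generics::augment
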
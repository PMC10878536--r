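#' Pooled training accuracy of a fitted predictor
#'
#' Fraction of all samples (pooled over datasets) whose predicted class
#' equals the stack's group label, with prediction from the omics
#' measurements only and ties at a zero score classified as control.
#'
#' @param fit A [poplsda()] fit (or [poplsda_params()]).
#' @param stack The [omics_stack()] the predictor was trained on.
#' @param groups Optional named list of label vectors overriding the
#'   stack's groups (used under permutation).
#' @return A number in `[0, 1]`.
#' @export
training_accuracy <- function(fit, stack, groups = NULL) {
  pred <- predict_params(if (inherits(fit, "poplsda_fit")) fit$params else fit,
                         stack)
  truth <- if (is.null(groups)) {
    unlist(lapply(stack$datasets, `[[`, "groups"), use.names = FALSE)
  } else {
    unlist(groups[names(stack$datasets)], use.names = FALSE)
  }
  mean(pred$class == truth)
}

#' Empirical p-value of perfect discrimination
#'
#' @param accuracies Numeric vector of per-permutation training accuracies.
#' @param conservative Use the (n_perfect + 1) / (B + 1) variant instead of
#'   the plain n_perfect / B proportion.
#' @return The empirical p-value.
#' @export
permutation_pvalue <- function(accuracies, conservative = FALSE) {
  B <- length(accuracies)
  n_perfect <- sum(accuracies >= 1)
  if (conservative) (n_perfect + 1) / (B + 1) else n_perfect / B
}

#' Permutation test of case/control discrimination
#'
#' Tests the null hypothesis of no relation between group labels and
#' features. For each of B permutations the labels are shuffled uniformly
#' at random within each dataset (preserving the per-dataset case/control
#' counts), the full pipeline is refit — model fit, top-`n_select` feature
#' selection, refit on the selected features — and the training accuracy on
#' the permuted labels is recorded. The p-value is the fraction of
#' permutations achieving perfect accuracy, matching the convention "one in
#' 400 permutations = 0.0025". Each permutation runs on an independent
#' seeded substream, so the result is reproducible and order-invariant.
#'
#' @param stack A standardized [omics_stack()].
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @param r,r_k Component numbers passed to [poplsda()].
#' @param n_select Number of features selected before the classification
#'   refit; `NULL` skips selection and scores the full fit.
#' @param n_starts,max_iter,tol EM options for the per-permutation refits
#'   (defaults favour speed: a single spectral start).
#' @param conservative Passed to [permutation_pvalue()].
#' @return An object of class `permutation_result`: list with `B`,
#'   `accuracies`, `n_perfect`, `p_value`, `seed`, `observed_accuracy`
#'   (accuracy of the unpermuted pipeline under the same options).
#' @export
permutation_test <- function(stack, B = 400, seed = 1, r = 2, r_k = 2,
                             n_select = NULL, n_starts = 1, max_iter = 200,
                             tol = 1e-5, conservative = FALSE) {
  stopifnot(inherits(stack, "omics_stack"), B >= 1)
  n_k <- vapply(stack$datasets, function(d) nrow(d$values), integer(1))
  n_arrangements <- prod(vapply(stack$datasets, function(d) {
    choose(nrow(d$values), sum(d$groups == "case"))
  }, numeric(1)))
  if (B > n_arrangements) {
    warning("B exceeds the number of distinct label arrangements (",
            format(n_arrangements), "); sampling with replacement")
  }
  perm_seeds <- make_substream_seeds(seed, B + 1L)

  run_pipeline <- function(groups, fit_seed) {
    y <- lapply(groups, function(g) ifelse(g == "case", 0.5, -0.5))
    fit <- poplsda(stack, r = r, r_k = r_k, y = y, max_iter = max_iter,
                   tol = tol, n_starts = n_starts, seed = fit_seed)
    if (!is.null(n_select)) {
      sel <- selected_features(select_top(rank_features(fit), n = n_select))
      sub <- subset_features(stack, sel)
      fit <- poplsda(sub, r = r, r_k = r_k, y = y, max_iter = max_iter,
                     tol = tol, n_starts = n_starts, seed = fit_seed)
      return(training_accuracy(fit, sub, groups = groups))
    }
    training_accuracy(fit, stack, groups = groups)
  }

  observed <- run_pipeline(lapply(stack$datasets, `[[`, "groups"),
                           perm_seeds[B + 1L])
  accuracies <- vapply(seq_len(B), function(b) {
    set.seed(perm_seeds[b])
    perm_groups <- lapply(stack$datasets, function(d) sample(d$groups))
    run_pipeline(perm_groups, perm_seeds[b])
  }, numeric(1))

  structure(
    list(B = B, accuracies = accuracies, n_perfect = sum(accuracies >= 1),
         p_value = permutation_pvalue(accuracies, conservative),
         conservative = conservative, seed = seed,
         observed_accuracy = observed,
         opts = list(r = r, r_k = r_k, n_select = n_select)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> B =", x$B, "\n")
  cat("  observed training accuracy:", format(x$observed_accuracy), "\n")
  cat("  permutations with perfect accuracy:", x$n_perfect, "\n")
  cat("  empirical p-value:", format(x$p_value),
      if (x$conservative) "(conservative)\n" else "\n")
  invisible(x)
}

#' Tidy a permutation result
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with one row per permutation: `permutation`, `accuracy`,
#'   `perfect`.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$B), accuracy = x$accuracies,
                 perfect = x$accuracies >= 1)
}

#' One-row summary of a permutation result
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return One-row tibble with `B`, `n_perfect`, `p_value`,
#'   `observed_accuracy`.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(B = x$B, n_perfect = x$n_perfect, p_value = x$p_value,
                 observed_accuracy = x$observed_accuracy)
}
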
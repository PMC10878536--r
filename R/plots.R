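#' Scree plot of stack eigenvalues
#'
#' @param stack A standardized [omics_stack()].
#' @param n_top Number of leading eigenvalues to show.
#' @return A ggplot.
#' @export
plot_scree <- function(stack, n_top = 10) {
  ev <- scree_eigenvalues(stack, n_top)
  df <- tibble::tibble(component = seq_along(ev), eigenvalue = ev)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Scree plot of the stacked datasets") +
    ggplot2::theme_minimal()
}

#' Sorted squared effect sizes with the selection cutoff
#'
#' @param object A `feature_ranking` (ideally after [select_top()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(.data$rank, .data$effect_sq)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Rank", y = expression((W * beta)^2),
                  title = "Sorted squared effect sizes") +
    ggplot2::theme_minimal()
  n_sel <- attr(object, "n_selected")
  if (!is.null(n_sel)) {
    gg <- gg + ggplot2::geom_vline(xintercept = n_sel, linetype = "dashed",
                                   colour = "darkgreen")
  }
  gg
}

#' Score predictions by dataset and group
#'
#' Boxplots of the per-sample predicted scores; positive scores read as
#' case, negative as control.
#'
#' @param object A [poplsda()] fit.
#' @param stack Optional stack to score (defaults to the training scores).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poplsda_fit <- function(object, stack = NULL, ...) {
  df <- augment.poplsda_fit(object, data = stack)
  if (!is.null(stack)) {
    df$group <- unlist(lapply(stack$datasets, `[[`, "groups"), use.names = FALSE)
  } else {
    df$group <- df$class
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$score,
                                   colour = .data$dataset)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge()) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.15)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "Predicted score") +
    ggplot2::theme_minimal()
}

#' Permutation accuracy histogram
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy.permutation_result(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$observed_accuracy,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Permutation training accuracy", y = "Count",
                  subtitle = sprintf("empirical p = %.4g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param object An `enrichment_table`.
#' @param n_top Number of top terms to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_table <- function(object, n_top = 10, ...) {
  df <- utils::head(object, n_top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$fdr), .data$term,
                                   size = .data$overlap)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL, size = "Overlap") +
    ggplot2::theme_minimal()
}
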
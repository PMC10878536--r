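#' Rank features by squared effect size
#'
#' Stable descending sort on the squared elements of the effect-size vector
#' W beta; ties are broken lexicographically on the feature ID so the
#' ranking is fully deterministic.
#'
#' @param effect_sizes Either the tibble returned by [effect_sizes()] (or a
#'   [poplsda()] fit) or a bare numeric vector together with `feature_ids`.
#' @param feature_ids Character vector, required for a bare numeric vector.
#' @return An object of class `feature_ranking`: a tibble with columns
#'   `rank`, `feature`, `effect`, `effect_sq` plus attributes filled in by
#'   [select_top()].
#' @export
rank_features <- function(effect_sizes, feature_ids = NULL) {
  if (inherits(effect_sizes, "poplsda_fit")) effect_sizes <- effect_sizes$effect_sizes
  if (is.numeric(effect_sizes)) {
    stopifnot(length(effect_sizes) == length(feature_ids))
    effect_sizes <- tibble::tibble(feature = as.character(feature_ids),
                                   effect = effect_sizes,
                                   effect_sq = effect_sizes^2)
  }
  tbl <- tibble::as_tibble(effect_sizes)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$effect_sq), .data$feature)
  tbl <- dplyr::mutate(tbl, rank = dplyr::row_number(), .before = 1)
  class(tbl) <- c("feature_ranking", class(tbl))
  tbl
}

#' Elbow of a non-increasing curve
#'
#' Automates the visual elbow rule: on the sorted curve, the elbow is the
#' index (0-based) maximizing the perpendicular distance to the chord
#' joining the first and last points; ties take the first index. A constant
#' curve has no elbow and returns 0 with a warning.
#'
#' @param sorted_values Non-increasing numeric vector, length >= 3.
#' @return Integer 0-based index of the elbow.
#' @export
elbow_index <- function(sorted_values) {
  v <- as.numeric(sorted_values)
  n <- length(v)
  if (n < 3L) stop("elbow_index needs at least 3 values")
  if (is.unsorted(rev(v), strictly = FALSE)) stop("values must be non-increasing")
  if (max(v) == min(v)) {
    warning("constant sequence has no elbow; returning 0")
    return(0L)
  }
  i <- seq_len(n) - 1
  # perpendicular distance from (i, v_i) to the chord (0, v_1)-(n-1, v_n)
  dx <- n - 1
  dy <- v[n] - v[1]
  dist <- abs(dy * i - dx * (v - v[1])) / sqrt(dx^2 + dy^2)
  as.integer(which.max(dist) - 1L)
}

#' Select the relevant feature set
#'
#' Marks the top `n` features as selected, or, when `n` is `NULL`, the top
#' `elbow_index + 1` features under the automatic elbow rule.
#'
#' @param ranking A [rank_features()] result.
#' @param n Optional number of features to keep (`1 <= n <= p`).
#' @return The ranking tibble with a logical `selected` column and
#'   attributes `elbow_index` and `n_selected`.
#' @export
select_top <- function(ranking, n = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"))
  p <- nrow(ranking)
  elbow <- if (p >= 3L) elbow_index(ranking$effect_sq) else 0L
  if (is.null(n)) {
    n <- elbow + 1L
  } else {
    if (n <= 0) stop("n must be positive")
    if (n > p) stop("n exceeds the number of features")
  }
  out <- dplyr::mutate(ranking, selected = .data$rank <= n)
  class(out) <- class(ranking)
  attr(out, "elbow_index") <- elbow
  attr(out, "n_selected") <- as.integer(n)
  out
}

#' Selected feature IDs of a ranking
#' @param ranking A [select_top()] result.
#' @return Character vector of selected features, in rank order.
#' @export
selected_features <- function(ranking) {
  if (!"selected" %in% names(ranking)) stop("run select_top() first")
  ranking$feature[ranking$selected]
}
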
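#' Construct a single-omics dataset
#'
#' An `omics_dataset` holds one omics layer: an `N x p` numeric matrix of
#' measurements (samples in rows, features in columns), per-sample
#' case/control labels, and the shared feature namespace (gene identifiers)
#' in column order.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param dataset_id Single string naming the layer (e.g. `"transcriptomics"`).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the rownames of `values`.
#' @param feature_ids Character vector of unique feature (gene) identifiers;
#'   defaults to the colnames of `values`.
#' @param groups Character vector with entries `"case"` / `"control"`, one
#'   per sample. Both groups must be present.
#'
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, dataset_id, sample_ids = rownames(values),
                          feature_ids = colnames(values), groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(sample_ids)) sample_ids <- paste0(dataset_id, "_s", seq_len(nrow(values)))
  if (is.null(feature_ids)) stop("feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  groups <- as.character(groups)
  if (length(dataset_id) != 1L || !nzchar(dataset_id)) {
    stop("`dataset_id` must be a single non-empty string")
  }
  if (nrow(values) != length(sample_ids)) stop("row count must equal length of sample_ids")
  if (nrow(values) != length(groups)) stop("row count must equal length of groups")
  if (ncol(values) != length(feature_ids)) stop("column count must equal length of feature_ids")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in dataset '", dataset_id, "'")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs in dataset '", dataset_id, "'")
  }
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad)) stop("groups must be 'case' or 'control', got: ", paste(bad, collapse = ", "))
  if (length(unique(groups)) < 2L) {
    stop("dataset '", dataset_id, "' must contain both cases and controls")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, dataset_id = dataset_id, sample_ids = sample_ids,
         feature_ids = feature_ids, groups = groups),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("<omics_dataset> ", x$dataset_id, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", sum(x$groups == "case"), " case / ",
      sum(x$groups == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Stack omics datasets sharing one feature namespace
#'
#' Vertical integration lays datasets with disjoint samples but identical
#' (identically ordered) features below each other. The stack is the unit all
#' modelling functions consume.
#'
#' @param datasets List of [omics_dataset()] objects with identical
#'   `feature_ids` in identical order and unique `dataset_id`s.
#'
#' @return An object of class `omics_stack` with elements `datasets` (named
#'   list) and `feature_ids`.
#' @export
omics_stack <- function(datasets) {
  if (inherits(datasets, "omics_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one dataset is required")
  if (!all(vapply(datasets, inherits, logical(1), "omics_dataset"))) {
    stop("all elements must be omics_dataset objects")
  }
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("dataset_ids must be unique")
  feats <- datasets[[1]]$feature_ids
  for (d in datasets[-1]) {
    if (!identical(d$feature_ids, feats)) {
      stop("all datasets must share identical, identically ordered feature_ids")
    }
  }
  names(datasets) <- ids
  structure(list(datasets = datasets, feature_ids = feats), class = "omics_stack")
}

#' @export
print.omics_stack <- function(x, ...) {
  cat("<omics_stack> ", length(x$datasets), " dataset(s), ",
      length(x$feature_ids), " shared features\n", sep = "")
  for (d in x$datasets) print(d)
  invisible(x)
}

#' Number of datasets, per-dataset sample sizes, feature count
#' @param stack An [omics_stack()].
#' @return `stack_dims()` returns a list with `K`, `n_k` (named integer
#'   vector) and `p`.
#' @export
stack_dims <- function(stack) {
  stopifnot(inherits(stack, "omics_stack"))
  list(
    K = length(stack$datasets),
    n_k = vapply(stack$datasets, function(d) nrow(d$values), integer(1)),
    p = length(stack$feature_ids)
  )
}

#' Restrict a stack to a subset of features
#'
#' @param stack An [omics_stack()].
#' @param features Character vector of feature IDs to keep (order taken from
#'   the stack, not from `features`).
#' @return An [omics_stack()] on the requested features.
#' @export
subset_features <- function(stack, features) {
  stopifnot(inherits(stack, "omics_stack"))
  keep <- stack$feature_ids %in% features
  if (!any(keep)) stop("no requested features present in the stack")
  omics_stack(lapply(stack$datasets, function(d) {
    omics_dataset(d$values[, keep, drop = FALSE], d$dataset_id,
                  d$sample_ids, d$feature_ids[keep], d$groups)
  }))
}

#' Tidy a stack into long format
#'
#' @param x An [omics_stack()].
#' @param ... Unused.
#' @return A tibble with columns `dataset`, `sample_id`, `group`, `feature`,
#'   `value`.
#' @export
tidy.omics_stack <- function(x, ...) {
  purrr::map_dfr(x$datasets, function(d) {
    tibble::tibble(
      dataset = d$dataset_id,
      sample_id = rep(d$sample_ids, times = ncol(d$values)),
      group = rep(d$groups, times = ncol(d$values)),
      feature = rep(d$feature_ids, each = nrow(d$values)),
      value = as.vector(d$values)
    )
  })
}

#' Sample metadata of a stack as a tibble
#' @param stack An [omics_stack()].
#' @return Tibble with columns `sample_id`, `dataset`, `group`.
#' @export
stack_metadata <- function(stack) {
  purrr::map_dfr(stack$datasets, function(d) {
    tibble::tibble(sample_id = d$sample_ids, dataset = d$dataset_id, group = d$groups)
  })
}

#' Numeric outcome encoding of the group labels
#'
#' Cases are coded +0.5 and controls -0.5, a zero-mean coding under balance
#' that matches the model's zero-mean Gaussian outcome; the classification
#' threshold is 0 (ties go to control).
#'
#' @param stack An [omics_stack()].
#' @return Named list (per dataset) of numeric vectors.
#' @export
encode_labels <- function(stack) {
  stopifnot(inherits(stack, "omics_stack"))
  lapply(stack$datasets, function(d) ifelse(d$groups == "case", 0.5, -0.5))
}
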
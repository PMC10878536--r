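#' Map platform features to a shared gene namespace and intersect datasets
#'
#' Each raw dataset is keyed by platform identifiers (probes, protein IDs).
#' Features are renamed to their mapped gene identifier, unmapped features
#' are dropped, many-to-one collisions within a dataset are resolved by
#' keeping the platform feature with the largest variance, and the datasets
#' are restricted to the genes present in every layer, sorted
#' lexicographically.
#'
#' @param raw_datasets List of [omics_dataset()] objects whose `feature_ids`
#'   are platform identifiers.
#' @param mapping Data frame with columns `platform_id`, `gene_id`; no
#'   platform ID may map to more than one gene.
#'
#' @return An [omics_stack()] on the intersected gene namespace.
#' @export
map_and_intersect <- function(raw_datasets, mapping) {
  if (inherits(raw_datasets, "omics_dataset")) raw_datasets <- list(raw_datasets)
  stopifnot(length(raw_datasets) >= 1L)
  mapping <- tibble::as_tibble(mapping)
  if (!all(c("platform_id", "gene_id") %in% names(mapping))) {
    stop("mapping must have columns platform_id and gene_id")
  }
  mapping <- dplyr::distinct(mapping, .data$platform_id, .data$gene_id)
  if (anyDuplicated(mapping$platform_id)) {
    stop("mapping is ambiguous: some platform_id maps to more than one gene_id")
  }
  if (any(!nzchar(mapping$gene_id) | is.na(mapping$gene_id))) {
    stop("mapping contains empty gene_id entries")
  }
  lut <- stats::setNames(mapping$gene_id, mapping$platform_id)

  mapped <- lapply(raw_datasets, function(d) {
    gene <- unname(lut[d$feature_ids])
    keep <- !is.na(gene)
    if (!any(keep)) {
      return(list(id = d$dataset_id, genes = character(0), data = NULL))
    }
    vals <- d$values[, keep, drop = FALSE]
    gene <- gene[keep]
    # collision rule: keep the highest-variance platform feature per gene
    v <- apply(vals, 2, stats::var)
    ord <- order(gene, -v, d$feature_ids[keep])
    first <- !duplicated(gene[ord])
    sel <- ord[first]
    vals <- vals[, sel, drop = FALSE]
    colnames(vals) <- gene[sel]
    list(id = d$dataset_id, genes = gene[sel], data = vals, src = d)
  })

  shared <- Reduce(intersect, lapply(mapped, `[[`, "genes"))
  if (!length(shared)) {
    counts <- vapply(mapped, function(m) length(m$genes), integer(1))
    ids <- vapply(mapped, `[[`, character(1), "id")
    stop("empty gene intersection across datasets (mapped counts: ",
         paste(sprintf("%s=%d", ids, counts), collapse = ", "), ")")
  }
  shared <- sort(shared)
  omics_stack(lapply(mapped, function(m) {
    omics_dataset(m$data[, shared, drop = FALSE], m$id,
                  m$src$sample_ids, shared, m$src$groups)
  }))
}

#' Variance filter on the inter-quartile range
#'
#' Retains exactly those features whose IQR exceeds the median of all
#' feature IQRs, preserving feature order. This removes the
#' least-variable half (or more, under ties) of the features.
#'
#' @param dataset An [omics_dataset()] with at least two samples.
#' @return The filtered [omics_dataset()].
#' @export
iqr_filter <- function(dataset) {
  stopifnot(inherits(dataset, "omics_dataset"))
  if (nrow(dataset$values) < 2L) stop("iqr_filter needs at least 2 samples")
  iqrs <- apply(dataset$values, 2, stats::IQR)
  keep <- iqrs > stats::median(iqrs)
  if (!any(keep)) stop("iqr_filter removed every feature")
  omics_dataset(dataset$values[, keep, drop = FALSE], dataset$dataset_id,
                dataset$sample_ids, dataset$feature_ids[keep], dataset$groups)
}

# Vectorised Welch two-sample t statistic (case minus control) per column.
# Returns 0 where the statistic is undefined (zero pooled standard error).
welch_t <- function(values, groups) {
  case <- values[groups == "case", , drop = FALSE]
  ctrl <- values[groups == "control", , drop = FALSE]
  n1 <- nrow(case); n0 <- nrow(ctrl)
  if (n1 < 1L || n0 < 1L) stop("both groups required")
  m1 <- colMeans(case); m0 <- colMeans(ctrl)
  v1 <- if (n1 > 1) apply(case, 2, stats::var) else rep(0, ncol(values))
  v0 <- if (n0 > 1) apply(ctrl, 2, stats::var) else rep(0, ncol(values))
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- (m1 - m0) / se
  t[!is.finite(t)] <- 0
  t
}

#' Harmonize effect-direction signs across omics layers
#'
#' Vertical integration assumes each gene's case/control effect points the
#' same way in every layer (e.g. mRNA and protein move together). For every
#' non-reference dataset and feature the Welch two-sample t statistic
#' (case minus control) is compared in sign against the reference dataset;
#' where the signs differ the feature's column is negated. Features with an
#' undefined or zero t statistic in either dataset are never flipped (a
#' warning counts them).
#'
#' @param stack An [omics_stack()] with both groups present in every layer.
#' @param reference `dataset_id` of the layer whose signs are kept.
#' @return The harmonized [omics_stack()]; the flip mask is attached as
#'   attribute `"flip_mask"` (named list of logical vectors) and retrievable
#'   with [flip_mask()].
#' @export
harmonize_signs <- function(stack, reference) {
  stopifnot(inherits(stack, "omics_stack"))
  if (!reference %in% names(stack$datasets)) {
    stop("reference dataset '", reference, "' not in stack")
  }
  ref <- stack$datasets[[reference]]
  t_ref <- welch_t(ref$values, ref$groups)
  n_undef <- 0L
  flips <- lapply(stack$datasets, function(d) {
    if (d$dataset_id == reference) {
      return(stats::setNames(rep(FALSE, length(d$feature_ids)), d$feature_ids))
    }
    t_d <- welch_t(d$values, d$groups)
    undef <- t_d == 0 | t_ref == 0
    n_undef <<- n_undef + sum(undef)
    flip <- !undef & (sign(t_d) != sign(t_ref))
    stats::setNames(flip, d$feature_ids)
  })
  if (n_undef > 0L) {
    warning(n_undef, " feature(s) had a zero/undefined t statistic and were left unflipped")
  }
  out <- omics_stack(lapply(stack$datasets, function(d) {
    f <- flips[[d$dataset_id]]
    vals <- d$values
    if (any(f)) vals[, f] <- -vals[, f, drop = FALSE]
    omics_dataset(vals, d$dataset_id, d$sample_ids, d$feature_ids, d$groups)
  }))
  attr(out, "flip_mask") <- flips
  out
}

#' @rdname harmonize_signs
#' @export
flip_mask <- function(stack) attr(stack, "flip_mask")

#' Standardize each dataset to zero mean, unit variance per feature
#'
#' Centering and scaling are per dataset and per feature, using the
#' unbiased (n - 1) variance. The centers and scales are attached so the
#' same transform can be applied to new data.
#'
#' @param stack An [omics_stack()]; every feature must have positive
#'   variance in every dataset.
#' @return The standardized [omics_stack()] with attribute `"scaling"` (per
#'   dataset list of `center` and `scale` vectors), retrievable with
#'   [scaling_params()].
#' @export
standardize_stack <- function(stack) {
  stopifnot(inherits(stack, "omics_stack"))
  scaling <- list()
  out <- omics_stack(lapply(stack$datasets, function(d) {
    ctr <- colMeans(d$values)
    sdv <- apply(d$values, 2, stats::sd)
    zero <- sdv <= 0 | !is.finite(sdv)
    if (any(zero)) {
      stop("zero-variance feature(s) in dataset '", d$dataset_id, "': ",
           paste(utils::head(d$feature_ids[zero], 5), collapse = ", "))
    }
    scaling[[d$dataset_id]] <<- list(center = ctr, scale = sdv)
    vals <- sweep(sweep(d$values, 2, ctr, "-"), 2, sdv, "/")
    omics_dataset(vals, d$dataset_id, d$sample_ids, d$feature_ids, d$groups)
  }))
  attr(out, "scaling") <- scaling
  out
}

#' @rdname standardize_stack
#' @export
scaling_params <- function(stack) attr(stack, "scaling")

#' Apply stored centers/scales to new data
#'
#' @param values Matrix (samples x features) on the stack's feature set.
#' @param scaling One dataset's entry of [scaling_params()].
#' @return The transformed matrix.
#' @export
apply_scaling <- function(values, scaling) {
  sweep(sweep(values, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper: map to the shared namespace and intersect,
#' optionally IQR-filter (before mapping, per raw dataset), harmonize signs
#' against a reference layer, and standardize.
#'
#' @inheritParams map_and_intersect
#' @inheritParams harmonize_signs
#' @param iqr Logical; apply [iqr_filter()] to each raw dataset first.
#' @return A standardized [omics_stack()] carrying `"flip_mask"` and
#'   `"scaling"` attributes.
#' @export
preprocess_stack <- function(raw_datasets, mapping, reference, iqr = FALSE) {
  if (iqr) raw_datasets <- lapply(raw_datasets, iqr_filter)
  stack <- map_and_intersect(raw_datasets, mapping)
  stack <- harmonize_signs(stack, reference)
  flips <- flip_mask(stack)
  stack <- standardize_stack(stack)
  attr(stack, "flip_mask") <- flips
  stack
}
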
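#' Read an expression matrix from TSV
#'
#' Layout: first column the feature ID, remaining columns one per sample,
#' header row of sample IDs; `#` comment lines ignored.
#'
#' @param path TSV file path.
#' @return A samples x features numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  feats <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  t(m)
}

#' Write an expression matrix to TSV (features x samples layout)
#' @param values Samples x features matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, path) {
  tbl <- tibble::as_tibble(t(values), rownames = "feature_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read sample metadata (columns sample_id, dataset, group)
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_metadata_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("sample_id", "dataset", "group")
  if (!all(need %in% names(tbl))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  tbl
}

#' Read a platform-to-gene feature mapping (columns platform_id, gene_id)
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_mapping_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("platform_id", "gene_id") %in% names(tbl))) {
    stop("mapping must have columns platform_id, gene_id")
  }
  tbl
}

#' Assemble raw omics datasets from expression files plus metadata
#'
#' @param expr_paths Named character vector of expression TSV paths (names
#'   are dataset ids; unnamed paths are named after the file).
#' @param metadata A metadata tibble or TSV path (see
#'   [read_metadata_tsv()]).
#' @return List of [omics_dataset()] objects.
#' @export
read_omics_datasets <- function(expr_paths, metadata) {
  if (is.character(metadata)) metadata <- read_metadata_tsv(metadata)
  if (is.null(names(expr_paths)) || any(!nzchar(names(expr_paths)))) {
    names(expr_paths) <- tools::file_path_sans_ext(basename(expr_paths))
  }
  lapply(names(expr_paths), function(id) {
    vals <- read_expression_tsv(expr_paths[[id]])
    meta <- metadata[metadata$dataset == id, , drop = FALSE]
    if (!nrow(meta)) stop("no metadata rows for dataset '", id, "'")
    missing <- setdiff(rownames(vals), meta$sample_id)
    if (length(missing)) {
      stop("samples without metadata in '", id, "': ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    meta <- meta[match(rownames(vals), meta$sample_id), , drop = FALSE]
    omics_dataset(vals, id, groups = meta$group)
  })
}

#' Write a (preprocessed) stack to a directory
#'
#' One expression TSV per dataset, a metadata TSV, and a JSON sidecar with
#' centers/scales and the sign-flip mask when present.
#'
#' @param stack An [omics_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_dir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in stack$datasets) {
    write_expression_tsv(d$values, file.path(dir, paste0(d$dataset_id, ".tsv")))
  }
  readr::write_tsv(stack_metadata(stack), file.path(dir, "metadata.tsv"))
  sidecar <- list(
    datasets = names(stack$datasets),
    scaling = scaling_params(stack),
    flip_mask = lapply(flip_mask(stack), function(f) names(f)[f])
  )
  jsonlite::write_json(sidecar, file.path(dir, "preprocess.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a stack written by [write_stack_dir()]
#' @param dir Directory path.
#' @return An [omics_stack()].
#' @export
read_stack_dir <- function(dir) {
  meta <- read_metadata_tsv(file.path(dir, "metadata.tsv"))
  ids <- unique(meta$dataset)
  paths <- stats::setNames(file.path(dir, paste0(ids, ".tsv")), ids)
  omics_stack(read_omics_datasets(paths, meta))
}

#' Serialize fitted parameters to JSON
#' @param fit A [poplsda()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  p <- fit$params
  out <- list(
    feature_ids = fit$feature_ids, r = fit$r, r_k = as.list(fit$r_k),
    W = p$W, P = p$P, beta = p$beta, sigma_u = p$sigma_u,
    sigma_v = p$sigma_v, sigma2_e = as.list(p$sigma2_e),
    sigma2_eps = p$sigma2_eps, loglik = fit$loglik,
    loglik_trace = fit$loglik_trace, converged = fit$converged,
    n_iter = fit$n_iter, seed = fit$seed,
    varexpl = fit$varexpl, effect_sizes = fit$effect_sizes
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
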
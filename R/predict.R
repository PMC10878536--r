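#' Predict outcome scores and classes from a fitted model
#'
#' The predicted score is \eqn{\hat y = \beta' E[u \mid x]}, conditioning on
#' the omics measurements only; a positive score is classified as a case,
#' non-positive (including exact ties at zero) as a control.
#'
#' @param object A [poplsda()] fit or [poplsda_params()].
#' @param newdata An [omics_stack()] (each dataset scored with its own
#'   specific loadings), or an N x p matrix together with `dataset`.
#' @param dataset Dataset id, index or `"pooled"`; required when `newdata`
#'   is a matrix.
#' @param ... Unused.
#' @return A tibble with columns `dataset`, `sample_id`, `score`, `class`
#'   (and `group` when `newdata` carries labels).
#' @export
predict.poplsda_fit <- function(object, newdata, dataset = NULL, ...) {
  predict_params(object$params, newdata, dataset)
}

#' @rdname predict.poplsda_fit
#' @export
predict.poplsda_params <- function(object, newdata, dataset = NULL, ...) {
  predict_params(object, newdata, dataset)
}

predict_params <- function(params, newdata, dataset = NULL) {
  if (inherits(newdata, "omics_stack")) {
    return(purrr::map_dfr(newdata$datasets, function(d) {
      id <- if (d$dataset_id %in% names(params$sigma2_e)) d$dataset_id else "pooled"
      sc <- drop(posterior_scores(params, d$values, id) %*% params$beta)
      tibble::tibble(dataset = d$dataset_id, sample_id = d$sample_ids,
                     group = d$groups, score = unname(sc),
                     class = ifelse(sc > 0, "case", "control"))
    }))
  }
  if (is.null(dataset)) stop("`dataset` is required when newdata is a matrix")
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  sc <- drop(posterior_scores(params, x, dataset) %*% params$beta)
  tibble::tibble(
    dataset = as.character(dataset),
    sample_id = if (!is.null(rownames(x))) rownames(x) else paste0("s", seq_len(nrow(x))),
    score = unname(sc), class = ifelse(sc > 0, "case", "control")
  )
}
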
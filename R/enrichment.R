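#' Over-representation analysis with the hypergeometric (Fisher) test
#'
#' For each term set the one-sided hypergeometric upper tail
#' \eqn{P(X \ge \mathrm{overlap})} is computed for the query genes against
#' the background, i.e. the one-sided Fisher exact test of
#' over-representation, followed by Benjamini-Hochberg adjustment across
#' all tested terms.
#'
#' Query genes outside the background are dropped with a warning; term sets
#' are intersected with the background before testing.
#'
#' @param query Character vector of query genes (e.g. selected features).
#' @param terms Named list of character vectors (term gene sets), e.g. from
#'   [read_gmt()].
#' @param background Character vector: the background gene universe.
#' @return A tibble of class `enrichment_table` with columns `term`,
#'   `term_size`, `overlap`, `query_size`, `background_size`, `p_value`,
#'   `fdr`, ranked by `fdr` then `p_value`.
#' @export
fisher_enrichment <- function(query, terms, background) {
  query <- unique(query)
  background <- unique(background)
  if (!length(background)) stop("empty background")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
    if (!length(query)) stop("no query genes remain inside the background")
  }
  if (!length(terms)) stop("no term sets supplied")
  if (is.null(names(terms))) stop("terms must be a named list")
  N <- length(background)
  n_q <- length(query)
  tbl <- purrr::map_dfr(names(terms), function(tm) {
    tset <- intersect(unique(terms[[tm]]), background)
    m <- length(tset)
    ov <- length(intersect(query, tset))
    p <- stats::phyper(ov - 1, m, N - m, n_q, lower.tail = FALSE)
    tibble::tibble(term = tm, term_size = m, overlap = ov,
                   query_size = n_q, background_size = N, p_value = p)
  })
  tbl$fdr <- stats::p.adjust(tbl$p_value, method = "BH")
  tbl <- dplyr::arrange(tbl, .data$fdr, .data$p_value, .data$term)
  class(tbl) <- c("enrichment_table", class(tbl))
  tbl
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT layout: term name, description, then the
#' member genes, one set per line.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Write gene sets in GMT format
#' @param terms Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(tm) {
    paste(c(tm, tm, terms[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
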
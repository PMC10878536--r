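#' Protein-protein interaction network
#'
#' Undirected gene graph stored with canonically ordered edges (no
#' self-loops, no duplicates), wrapping an igraph object for traversal.
#'
#' @param edges Data frame with columns `gene1`, `gene2` and optionally
#'   `score` (confidence in `[0, 1]`).
#' @param nodes Optional character vector of additional isolated nodes.
#' @return An object of class `ppi_network` with elements `edges` (tibble),
#'   `nodes` and `graph` (igraph).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene1", "gene2") %in% names(edges)))
  self <- edges$gene1 == edges$gene2
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  a <- pmin(edges$gene1, edges$gene2)
  b <- pmax(edges$gene1, edges$gene2)
  edges$gene1 <- a; edges$gene2 <- b
  edges <- dplyr::distinct(edges, .data$gene1, .data$gene2, .keep_all = TRUE)
  all_nodes <- sort(unique(c(edges$gene1, edges$gene2, nodes)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene1", "gene2")], directed = FALSE,
    vertices = data.frame(name = all_nodes)
  )
  structure(list(edges = edges, nodes = all_nodes, graph = g),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network>", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Load an interaction network from an edge table
#'
#' Reads a tab-separated edge list (`gene1`, `gene2`, optional
#' `combined_score`/`score`), keeps edges at or above the confidence
#' threshold (all edges when no score column is present), canonicalizes
#' and deduplicates, and drops self-loops with a warning.
#'
#' @param path TSV file path (or a data frame used as-is). `#` comment
#'   lines are ignored.
#' @param threshold Minimum confidence score to keep an edge (default 0.4,
#'   the usual medium-evidence cutoff).
#' @return A [ppi_network()].
#' @export
load_network <- function(path, threshold = 0.4) {
  edges <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  }
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  names(edges)[1:2] <- c("gene1", "gene2")
  if (ncol(edges) >= 3L) names(edges)[3] <- "score"
  bad <- !stats::complete.cases(edges[, 1:2]) |
    !nzchar(edges$gene1) | !nzchar(edges$gene2)
  if (any(bad)) stop("malformed edge record at line(s): ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  if ("score" %in% names(edges)) {
    if (!is.numeric(edges$score)) stop("score column must be numeric")
    edges <- edges[edges$score >= threshold, , drop = FALSE]
  }
  ppi_network(edges)
}

#' Expand drug target sets by their direct network neighbors
#'
#' For each drug the expanded gene set is the union of its targets and all
#' genes adjacent to a target in the interaction network (a depth-1
#' breadth-first expansion). Targets absent from the network contribute no
#' neighbors but stay in the set; their per-drug counts are reported in the
#' attribute `"n_missing"`.
#'
#' @param drug_targets Data frame with columns `drug`, `gene` (one target
#'   per row).
#' @param network A [ppi_network()].
#' @return Tibble with columns `drug`, `gene`, `is_target` (FALSE for genes
#'   added by the expansion).
#' @export
expand_targets <- function(drug_targets, network) {
  stopifnot(inherits(network, "ppi_network"))
  dt <- tibble::as_tibble(drug_targets)
  stopifnot(all(c("drug", "gene") %in% names(dt)))
  if (!nrow(dt)) stop("empty drug-target table")
  adj <- igraph::adjacent_vertices(
    network$graph,
    v = intersect(unique(dt$gene), network$nodes)
  )
  adj <- lapply(adj, function(v) names(v))
  n_missing <- integer(0)
  out <- purrr::map_dfr(split(dt$gene, dt$drug), function(targets) {
    targets <- unique(targets)
    nb <- unique(unlist(adj[intersect(targets, names(adj))], use.names = FALSE))
    genes <- union(targets, nb)
    tibble::tibble(gene = genes, is_target = genes %in% targets)
  }, .id = "drug")
  miss <- vapply(split(dt$gene, dt$drug),
                 function(g) sum(!unique(g) %in% network$nodes), integer(1))
  attr(out, "n_missing") <- miss
  out
}

#' Count drug-gene links within the relevant gene set
#'
#' Given expanded per-drug gene sets, counts for every relevant gene the
#' number of drugs whose expanded set contains it (the "halo" intensity)
#' and for every drug the number of relevant genes it (indirectly) targets
#' (its direct interactors). By the bipartite handshake identity the two
#' count totals agree.
#'
#' @param expanded Tibble from [expand_targets()] (columns `drug`, `gene`).
#' @param relevant Non-empty character vector of relevant gene IDs.
#' @param exclude_self_targets Count only neighbor genes, not the drug's
#'   own targets (requires the `is_target` column; default FALSE).
#' @return List with tibbles `genes` (`gene`, `n_drugs`; all relevant
#'   genes, zero-filled) and `drugs` (`drug`, `n_direct_interactors`).
#' @export
count_links <- function(expanded, relevant, exclude_self_targets = FALSE) {
  if (!length(relevant)) stop("relevant gene set is empty")
  ex <- tibble::as_tibble(expanded)
  if (exclude_self_targets) {
    if (!"is_target" %in% names(ex)) stop("is_target column required")
    ex <- ex[!ex$is_target, , drop = FALSE]
  }
  hits <- dplyr::distinct(ex[ex$gene %in% relevant, c("drug", "gene")])
  genes <- dplyr::count(hits, .data$gene, name = "n_drugs")
  genes <- dplyr::left_join(tibble::tibble(gene = sort(unique(relevant))),
                            genes, by = "gene")
  genes$n_drugs[is.na(genes$n_drugs)] <- 0L
  drugs <- dplyr::count(hits, .data$drug, name = "n_direct_interactors")
  drugs <- dplyr::left_join(tibble::tibble(drug = sort(unique(ex$drug))),
                            drugs, by = "drug")
  drugs$n_direct_interactors[is.na(drugs$n_direct_interactors)] <- 0L
  list(genes = dplyr::arrange(genes, dplyr::desc(.data$n_drugs), .data$gene),
       drugs = dplyr::arrange(drugs, dplyr::desc(.data$n_direct_interactors),
                              .data$drug))
}
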
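test_that("load_network filters by score, canonicalizes and drops self-loops", {
  edges <- tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "c"),
                          score = c(0.9, 0.2))
  net <- load_network(edges, threshold = 0.4)
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$gene1, "a")
  # duplicates in either orientation collapse to one edge
  dup <- tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "a"))
  expect_equal(nrow(ppi_network(dup)$edges), 1)
  # self-loop dropped with a warning
  expect_warning(net2 <- ppi_network(tibble::tibble(gene1 = "a", gene2 = "a",
                                                    score = 0.9)),
                 "1 self-loop")
  expect_equal(nrow(net2$edges), 0)
})

test_that("load_network reads TSV and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "gene1\tgene2\tscore", "a\tb\t0.8", "b\tc\t0.3"), f)
  net <- load_network(f, threshold = 0.4)
  expect_equal(nrow(net$edges), 1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene1\tgene2", "a\tb", "x\t"), f2)
  expect_error(load_network(f2), "malformed")
})

test_that("expand_targets is a depth-1 BFS including the targets themselves", {
  net <- ppi_network(tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "c")))
  ex <- expand_targets(tibble::tibble(drug = "D", gene = "a"), net)
  expect_setequal(ex$gene, c("a", "b"))
  expect_true(ex$is_target[ex$gene == "a"])
  expect_false(ex$is_target[ex$gene == "b"])
  # target absent from the network stays in the set with no neighbors
  ex2 <- expand_targets(tibble::tibble(drug = "D", gene = "x"), net)
  expect_identical(ex2$gene, "x")
  expect_equal(attr(ex2, "n_missing")[["D"]], 1L)
})

test_that("expansion and counting match brute-force oracles on random fixtures", {
  for (seed in 1:10) {
    fx <- fixture_network(n_genes = 12, n_drugs = 5, edge_prob = 0.25,
                          seed = seed)
    ex <- expand_targets(fx$drug_targets, fx$network)
    # brute-force one-step BFS over the raw edge tibble
    el <- fx$network$edges
    nb <- function(g) unique(c(el$gene2[el$gene1 == g], el$gene1[el$gene2 == g]))
    for (d in unique(fx$drug_targets$drug)) {
      targets <- unique(fx$drug_targets$gene[fx$drug_targets$drug == d])
      want <- unique(c(targets, unlist(lapply(targets, nb))))
      expect_setequal(ex$gene[ex$drug == d], want)
    }
    # brute-force double loop for the counts
    set.seed(seed + 500)
    relevant <- sample(fx$network$nodes, 6)
    cnt <- count_links(ex, relevant)
    sets <- split(ex$gene, ex$drug)
    for (g in relevant) {
      expect_equal(cnt$genes$n_drugs[cnt$genes$gene == g],
                   sum(vapply(sets, function(s) g %in% s, logical(1))))
    }
    for (d in names(sets)) {
      expect_equal(cnt$drugs$n_direct_interactors[cnt$drugs$drug == d],
                   length(intersect(sets[[d]], relevant)))
    }
    # handshake identity
    expect_equal(sum(cnt$genes$n_drugs), sum(cnt$drugs$n_direct_interactors))
  }
})

test_that("expansion is monotone in the edge set", {
  edges <- tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "c"))
  dt <- tibble::tibble(drug = c("D1", "D2"), gene = c("a", "c"))
  small <- expand_targets(dt, ppi_network(edges))
  grown <- expand_targets(dt, ppi_network(dplyr::bind_rows(
    edges, tibble::tibble(gene1 = "a", gene2 = "c"))))
  for (d in c("D1", "D2")) {
    expect_true(all(small$gene[small$drug == d] %in%
                      grown$gene[grown$drug == d]))
  }
})

test_that("count_links respects the exclude-self-targets flag", {
  ex <- tibble::tibble(drug = c("D1", "D1", "D2"),
                       gene = c("a", "b", "b"),
                       is_target = c(TRUE, FALSE, FALSE))
  cnt <- count_links(ex, c("a", "b"))
  expect_equal(cnt$genes$n_drugs[cnt$genes$gene == "a"], 1L)
  expect_equal(cnt$drugs$n_direct_interactors[cnt$drugs$drug == "D1"], 2L)
  cnt2 <- count_links(ex, c("a", "b"), exclude_self_targets = TRUE)
  expect_equal(cnt2$genes$n_drugs[cnt2$genes$gene == "a"], 0L)
  expect_equal(cnt2$drugs$n_direct_interactors[cnt2$drugs$drug == "D1"], 1L)
  expect_error(count_links(ex, character(0)), "empty")
})

test_that("fixture networks hit the boundary cases deterministically", {
  none <- fixture_network(n_genes = 8, n_drugs = 2, edge_prob = 0, seed = 1)
  expect_equal(nrow(none$network$edges), 0)
  full <- fixture_network(n_genes = 8, n_drugs = 2, edge_prob = 1, seed = 1)
  expect_equal(nrow(full$network$edges), 8 * 7 / 2)
  a <- fixture_network(n_genes = 10, n_drugs = 3, edge_prob = 0.3, seed = 9)
  b <- fixture_network(n_genes = 10, n_drugs = 3, edge_prob = 0.3, seed = 9)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$drug_targets, b$drug_targets)
})
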
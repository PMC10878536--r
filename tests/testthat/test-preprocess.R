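test_that("map_and_intersect intersects mapped genes and sorts them", {
  d1 <- omics_dataset(matrix(rnorm(8), 2, 4), "a",
                      feature_ids = c("p1", "p2", "p3", "p4"),
                      groups = c("case", "control"))
  d2 <- omics_dataset(matrix(rnorm(8), 2, 4), "b",
                      feature_ids = c("q1", "q2", "q3", "q4"),
                      groups = c("case", "control"))
  mapping <- tibble::tibble(platform_id = c("p1", "p2", "q1", "q2"),
                            gene_id = c("g1", "g2", "g2", "g3"))
  stack <- map_and_intersect(list(d1, d2), mapping)
  expect_identical(stack$feature_ids, "g2")
  expect_equal(stack$datasets$a$values[, "g2"], unname(d1$values[, "p2"]),
               ignore_attr = TRUE)

  # single dataset, identity mapping -> features sorted
  d3 <- omics_dataset(matrix(rnorm(6), 2, 3), "c",
                      feature_ids = c("z", "a", "m"),
                      groups = c("case", "control"))
  idmap <- tibble::tibble(platform_id = c("z", "a", "m"),
                          gene_id = c("z", "a", "m"))
  st3 <- map_and_intersect(list(d3), idmap)
  expect_identical(st3$feature_ids, c("a", "m", "z"))

  # empty intersection is a hard error naming per-dataset counts
  map2 <- tibble::tibble(platform_id = c("p1", "q1"), gene_id = c("g1", "g9"))
  expect_error(map_and_intersect(list(d1, d2), map2), "empty gene intersection")
})

test_that("many-to-one collisions keep the highest-variance platform feature", {
  # p1, p2 both map to g1; p1 has the larger variance
  vals <- cbind(p1 = c(0, 2, 4, 6), p2 = c(1, 2, 3, 4))
  stopifnot(var(vals[, "p1"]) > var(vals[, "p2"]))  # brute-force check
  dA <- omics_dataset(vals, "A", groups = c("case", "case", "control", "control"))
  dB <- omics_dataset(cbind(q1 = rnorm(4)), "B",
                      groups = c("case", "case", "control", "control"))
  mapping <- tibble::tibble(platform_id = c("p1", "p2", "q1"),
                            gene_id = c("g1", "g1", "g1"))
  stack <- map_and_intersect(list(dA, dB), mapping)
  expect_identical(stack$feature_ids, "g1")
  expect_equal(unname(stack$datasets$A$values[, "g1"]), unname(vals[, "p1"]))
})

test_that("map_and_intersect is insensitive to input feature order", {
  d1 <- omics_dataset(matrix(rnorm(12), 3, 4), "a",
                      feature_ids = c("p1", "p2", "p3", "p4"),
                      groups = c("case", "control", "case"))
  perm <- c(3, 1, 4, 2)
  d1p <- omics_dataset(d1$values[, perm], "a",
                       feature_ids = d1$feature_ids[perm],
                       groups = d1$groups)
  mapping <- tibble::tibble(platform_id = paste0("p", 1:4),
                            gene_id = paste0("g", 1:4))
  s1 <- map_and_intersect(list(d1), mapping)
  s2 <- map_and_intersect(list(d1p), mapping)
  expect_equal(s1$datasets$a$values, s2$datasets$a$values)
})

test_that("iqr_filter keeps exactly the features with IQR above the median IQR", {
  # 4 features engineered so IQRs are (0, 0, 2, 2): median IQR = 1
  vals <- cbind(f1 = rep(5, 4), f2 = rep(-1, 4),
                f3 = c(0, 1, 2, 3) * 4 / 3, f4 = c(2, 3, 4, 5) * 4 / 3)
  iqrs <- apply(vals, 2, IQR)  # reference quantile routine
  expect_equal(unname(iqrs), c(0, 0, 2, 2))
  d <- omics_dataset(vals, "d", groups = c("case", "control", "case", "control"))
  kept <- iqr_filter(d)
  expect_identical(kept$feature_ids, c("f3", "f4"))

  # all-constant features: none exceed the median of zeros -> error
  dc <- omics_dataset(matrix(1, 3, 3), "d",
                      feature_ids = paste0("f", 1:3),
                      groups = c("case", "control", "case"))
  expect_error(iqr_filter(dc), "every feature")

  # a single feature can never exceed its own median IQR
  d1 <- omics_dataset(matrix(c(1, 5, 9), 3, 1), "d", feature_ids = "f1",
                      groups = c("case", "control", "case"))
  expect_error(iqr_filter(d1), "every feature")
})

test_that("harmonize_signs flips discordant features and is idempotent", {
  set.seed(7)
  p <- 10
  base <- matrix(rnorm(12 * p), 12, p)
  grp <- rep(c("case", "control"), each = 6)
  # dataset 1 (reference): cases shifted +2 on all features
  m1 <- base + outer(as.numeric(grp == "case"), rep(2, p))
  # dataset 2: discordant on features 3 and 7 (cases shifted -3 there)
  dir2 <- rep(2, p); dir2[c(3, 7)] <- -3
  m2 <- matrix(rnorm(12 * p), 12, p) + outer(as.numeric(grp == "case"), dir2)
  d1 <- toy_dataset(m1, "ref", groups = grp)
  d2 <- toy_dataset(m2, "other", groups = grp)
  st <- omics_stack(list(d1, d2))
  out <- harmonize_signs(st, "ref")
  flips <- flip_mask(out)
  expect_false(any(flips$ref))
  expect_setequal(names(which(flips$other)), c("g3", "g7"))
  expect_equal(out$datasets$other$values[, "g3"], -d2$values[, "g3"])

  # re-computed t signs now agree with the reference everywhere
  t_ref <- apply(out$datasets$ref$values, 2, function(x)
    t.test(x[grp == "case"], x[grp == "control"])$statistic)
  t_oth <- apply(out$datasets$other$values, 2, function(x)
    t.test(x[grp == "case"], x[grp == "control"])$statistic)
  expect_true(all(sign(t_ref) == sign(t_oth)))

  # idempotence: a second application changes nothing
  out2 <- harmonize_signs(out, "ref")
  expect_equal(out2$datasets$other$values, out$datasets$other$values)
  expect_false(any(flip_mask(out2)$other))

  # the flip mask applied to the raw data reproduces the harmonized data
  manual <- d2$values
  manual[, flips$other] <- -manual[, flips$other]
  expect_equal(out$datasets$other$values, manual)
})

test_that("harmonize_signs never flips on a zero/undefined t statistic", {
  grp <- c("case", "case", "control", "control")
  m1 <- cbind(g1 = c(5, 5, 1, 1), g2 = c(1, 2, 3, 4))
  m2 <- cbind(g1 = c(0, 0, 0, 0), g2 = c(4, 3, 2, 1))  # g1 constant: t undefined
  st <- omics_stack(list(toy_dataset(m1, "ref", groups = grp),
                         toy_dataset(m2, "other", groups = grp)))
  expect_warning(out <- harmonize_signs(st, "ref"), "unflipped")
  expect_false(flip_mask(out)$other[["g1"]])
  expect_true(flip_mask(out)$other[["g2"]])
})

test_that("standardize_stack gives per-dataset zero mean and unit variance", {
  st <- toy_stack(p = 5)
  std <- standardize_stack(st)
  for (d in std$datasets) {
    expect_true(max(abs(colMeans(d$values))) < 1e-12)
    expect_true(max(abs(apply(d$values, 2, var) - 1)) < 1e-10)
  }
  # closed form on a tiny column
  one <- toy_dataset(cbind(g1 = c(1, 2, 3), g2 = c(0, 1, 3)),
                     groups = c("case", "control", "case"))
  sd1 <- standardize_stack(omics_stack(list(one)))
  expect_equal(unname(sd1$datasets$omics1$values[, "g1"]),
               (c(1, 2, 3) - 2) / 1)
  # already standardized data are a fixed point
  sd2 <- standardize_stack(sd1)
  expect_equal(sd2$datasets$omics1$values, sd1$datasets$omics1$values,
               tolerance = 1e-12)
  # per-dataset centering forces the pooled mean to zero as well, but the
  # pooled variance differs from 1 (per-dataset unit variances do not pool)
  stdm <- do.call(rbind, lapply(std$datasets, `[[`, "values"))
  expect_lt(max(abs(colMeans(stdm))), 1e-12)
  expect_gt(max(abs(apply(stdm, 2, var) - 1)), 1e-4)
  # zero-variance feature is a hard error naming the feature
  zv <- toy_dataset(cbind(g1 = c(1, 1, 1), g2 = c(0, 1, 3)),
                    groups = c("case", "control", "case"))
  expect_error(standardize_stack(omics_stack(list(zv))), "g1")
})

test_that("sign harmonization commutes with standardization up to column signs", {
  set.seed(11)
  grp <- rep(c("case", "control"), each = 5)
  m1 <- matrix(rnorm(10 * 6), 10, 6) + outer(as.numeric(grp == "case"), rep(1.5, 6))
  dir2 <- c(1.5, -1.5, 1.5, -1.5, 1.5, 1.5)
  m2 <- matrix(rnorm(10 * 6), 10, 6) + outer(as.numeric(grp == "case"), dir2)
  st <- omics_stack(list(toy_dataset(m1, "ref", groups = grp),
                         toy_dataset(m2, "other", groups = grp)))
  a <- standardize_stack(harmonize_signs(st, "ref"))
  b <- harmonize_signs(standardize_stack(st), "ref")
  for (id in names(st$datasets)) {
    expect_equal(abs(a$datasets[[id]]$values), abs(b$datasets[[id]]$values),
                 tolerance = 1e-10)
  }
})

test_that("apply_scaling reproduces the stored transform on new data", {
  st <- toy_stack(p = 4)
  std <- standardize_stack(st)
  sc <- scaling_params(std)$omics1
  expect_equal(apply_scaling(st$datasets$omics1$values, sc),
               std$datasets$omics1$values)
})
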
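test_that("expression matrices round-trip through TSV", {
  v <- matrix(c(1.5, 2, 3, 4.25, 5, 6), 3, 2)
  d <- make_dataset(v, state = "raw", gene_ids = c("YAL001C", "YAL002W",
                                                   "YAL003W"),
                    conditions = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(d, path)
  d2 <- read_expression_matrix(path, dataset_id = d$dataset_id)
  expect_equal(d2$values, d$values)
  expect_identical(d2$gene_ids, d$gene_ids)
  expect_identical(d2$condition_labels, d$condition_labels)
  expect_identical(d2$state, "raw")
})

test_that("malformed input files raise precise parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "YAL001C\t1\t2", "YAL001C\t3\t4"), path)
  expect_error(read_expression_matrix(path), "YAL001C")
  writeLines(c("s1\ts2", "g1\t1\t2", "g2\t3"), path)
  expect_error(read_expression_matrix(path), "line 3")
  writeLines(c("s1\ts2", "g1\t1\tx", "g2\t3\t4"), path)
  expect_error(read_expression_matrix(path), "line 2")
})

test_that("gene-universe alignment reorders, drops, and errors as configured", {
  d1 <- make_dataset(matrix(1:4, 2, 2), state = "raw",
                     gene_ids = c("g2", "g1"))
  d2 <- make_dataset(matrix(1:6, 3, 2), state = "raw",
                     gene_ids = c("g1", "g2", "g3"))
  al <- align_gene_universe(list(d1, d2), c("g1", "g2"))
  expect_identical(al$datasets[[1]]$gene_ids, c("g1", "g2"))
  expect_identical(al$datasets[[2]]$gene_ids, c("g1", "g2"))
  expect_equal(al$datasets[[1]]$values["g1", ], d1$values["g1", ])
  expect_error(align_gene_universe(list(d1, d2), c("g1", "g3")), "g3")
  al2 <- align_gene_universe(list(d1, d2), c("g1", "g3"),
                             mode = "intersection")
  expect_identical(al2$universe, "g1")
})

test_that("quantile normalization matches the rank-mean procedure", {
  d <- make_dataset(cbind(c(1, 3), c(2, 4)), state = "raw")
  q <- quantile_normalize(d)
  expect_equal(unname(q$values), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # fixed point: identical columns
  d2 <- make_dataset(cbind(c(5, 1, 3), c(5, 1, 3)), state = "raw")
  expect_equal(quantile_normalize(d2)$values, d2$values)
  expect_identical(quantile_normalize(d2)$state, "normalized")
})

test_that("quantile-normalized columns share one value multiset", {
  set.seed(11)
  for (rep in 1:5) {
    d <- make_dataset(matrix(rexp(30 * 4), 30, 4), state = "raw")
    q <- quantile_normalize(d)$values
    for (j in 2:ncol(q))
      expect_equal(sort(unname(q[, 1])), sort(unname(q[, j])))
    # within-column ranks preserved
    expect_identical(apply(q, 2, rank), apply(d$values, 2, rank))
  }
})

test_that("single-column datasets pass through normalization with a warning", {
  d <- make_dataset(matrix(1:3, 3, 1), state = "raw")
  expect_warning(q <- quantile_normalize(d), "no-op")
  expect_equal(q$values, d$values)
})

test_that("replicate summarization takes per-condition medians", {
  d <- make_dataset(matrix(c(1, 3, 100), 1, 3), state = "normalized",
                    conditions = c("a1", "a2", "a3"))
  map <- data.frame(sample = c("a1", "a2", "a3"),
                    condition = c("t0", "t0", "t0"))
  s <- summarize_replicates(d, map)
  expect_equal(unname(s$values), matrix(3, 1, 1))  # robust to the outlier
  # even-sized group -> midpoint
  d2 <- make_dataset(matrix(c(1, 2), 1, 2), state = "normalized",
                     conditions = c("b1", "b2"))
  map2 <- data.frame(sample = c("b1", "b2"), condition = c("t0", "t0"))
  expect_equal(unname(summarize_replicates(d2, map2)$values),
               matrix(1.5, 1, 1))
  # singleton groups: identity, condition order = first appearance
  d3 <- make_dataset(matrix(1:4, 2, 2), state = "normalized",
                     conditions = c("x", "y"))
  s3 <- summarize_replicates(d3)
  expect_equal(unname(s3$values), unname(d3$values))
  expect_identical(s3$condition_labels, c("x", "y"))
})

test_that("gene standardization uses the population-SD convention", {
  d <- make_dataset(matrix(c(1, 2, 3), 1, 3), state = "summarized")
  s <- standardize_genes(d)
  expect_equal(unname(s$values[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # constant row: zero-filled and flagged, not dropped
  d2 <- make_dataset(rbind(c(5, 5, 5), c(1, 2, 6)), state = "summarized")
  s2 <- standardize_genes(d2)
  expect_equal(unname(s2$values[1, ]), c(0, 0, 0))
  expect_identical(s2$flagged_genes, "g001")
  expect_equal(nrow(s2$values), 2L)
})

test_that("standardized rows have zero mean and unit SD or are flagged", {
  set.seed(3)
  d <- make_dataset(matrix(rnorm(50 * 6, 5, 2), 50, 6),
                    state = "summarized")
  s <- standardize_genes(d)
  expect_true(all(abs(rowMeans(s$values)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(s$values^2)) - 1) < 1e-9))
  # idempotence
  s2 <- standardize_genes(s)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
})

test_that("the preprocessing chain enforces its stage order", {
  d <- make_dataset(matrix(rexp(12), 3, 4), state = "raw")
  expect_error(standardize_genes(d), "state")
  expect_error(summarize_replicates(d), "state")
  n <- quantile_normalize(d)
  expect_error(quantile_normalize(n), "state")
  p <- preprocess_dataset(d)
  expect_identical(p$state, "standardized")
  expect_length(attr(p, "log"), 4L)
})

test_that("per-delta membership tables serialize with '-' for unassigned", {
  m <- rbind(c(0.8, 0.55, 1), c(0.2, 0.45, 0))
  colnames(m) <- c("gA", "gB", "gC")
  cp <- copam(m, "final")
  sw <- delta_sweep(cp, c(0, 0.3, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_membership_table(sw, path)
  tab <- read_membership_table(path)
  expect_identical(tab$gene, c("gA", "gB", "gC"))
  expect_identical(unname(unlist(tab[tab$gene == "gB", -1])),
                   c("C1", "-", "-"))
  expect_identical(unname(unlist(tab[tab$gene == "gC", -1])),
                   c("C1", "C1", "C1"))
  # round-trip: labels match the partitions they came from
  for (i in seq_along(sw$partitions)) {
    p <- sw$partitions[[i]]
    lab <- tab[[i + 1L]]
    assigned <- colSums(p$membership) == 1
    expect_identical(lab == "-", unname(!assigned))
  }
})
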
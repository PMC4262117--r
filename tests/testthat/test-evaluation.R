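test_that("per-gene MSE matches hand-derived values", {
  # singleton cluster: profile equals centroid
  d <- make_dataset(zscore_rows(matrix(rnorm(3 * 6), 3, 6)), id = "D1")
  p <- hard_partition(c(1, 2, 2), K = 2, gene_ids = d$gene_ids)
  bp <- binarized_partition(p$membership, "DTB", 0)
  expect_equal(mse_cluster(bp, d, 1), 0)
  # opposite population-z-scored pair: centroid 0, MSE exactly 1
  x1 <- zscore_rows(matrix(rnorm(1 * 8), 1, 8))
  d2 <- make_dataset(rbind(x1, -x1), id = "D2")
  p2 <- hard_partition(c(1, 1), K = 2, gene_ids = d2$gene_ids)
  bp2 <- binarized_partition(p2$membership, "DTB", 0)
  expect_equal(mse_cluster(bp2, d2, 1), 1, tolerance = 1e-12)
  # empty cluster: undefined, never zero
  expect_true(is.na(mse_cluster(bp2, d2, 2)))
})

test_that("MSE equals the naive double-loop oracle", {
  set.seed(51)
  for (rep in 1:5) {
    x <- zscore_rows(matrix(rnorm(20 * 7), 20, 7))
    d <- make_dataset(x, id = "D1")
    p <- hard_partition(rep(1L, 20), K = 1, gene_ids = d$gene_ids)
    bp <- binarized_partition(p$membership, "DTB", 0)
    expect_equal(mse_cluster(bp, d, 1), mse_oracle(x), tolerance = 1e-12)
  }
})

test_that("MSE is invariant to gene order within the cluster", {
  set.seed(52)
  x <- zscore_rows(matrix(rnorm(10 * 5), 10, 5))
  d <- make_dataset(x)
  perm <- sample(10)
  dp <- make_dataset(x[perm, ], gene_ids = d$gene_ids[perm])
  p <- binarized_partition(matrix(1L, 1, 10,
                                  dimnames = list("C1", d$gene_ids)),
                           "DTB", 0)
  expect_equal(mse_cluster(p, d, 1), mse_cluster(p, dp, 1),
               tolerance = 1e-12)
})

test_that("MSE report averages per-dataset values over datasets", {
  set.seed(53)
  d1 <- make_dataset(zscore_rows(matrix(rnorm(12 * 5), 12, 5)), id = "D1")
  d2 <- make_dataset(zscore_rows(matrix(rnorm(12 * 9), 12, 9)), id = "D2")
  m <- rbind(rep(c(1, 0), each = 6), rep(c(0, 1), each = 6)) * 1.0
  colnames(m) <- d1$gene_ids
  sw <- delta_sweep(copam(m, "final"), c(0, 1))
  r1 <- mse_report(sw, list(d1))
  expect_equal(r1$summary$mean_mse, r1$per_dataset$mse[
    match(paste(r1$summary$delta, r1$summary$cluster),
          paste(r1$per_dataset$delta, r1$per_dataset$cluster))])
  # duplicating the dataset list leaves the mean unchanged
  r2 <- mse_report(sw, list(d1, d1))
  expect_equal(r2$summary$mean_mse, r1$summary$mean_mse)
  # two datasets: mean is the arithmetic average
  r12 <- mse_report(sw, list(d1, d2))
  expect_equal(r12$summary$mean_mse[1],
               mean(r12$per_dataset$mse[r12$per_dataset$delta == 0 &
                                        r12$per_dataset$cluster == "C1"]))
})

test_that("tightness ranking orders by retention delta then size", {
  counts <- cbind(C1 = c(1085L, 516L, 344L, 257L, 164L, 79L),
                  C2 = c(145L, 394L, 47L, 0L, 0L, 0L),
                  C3 = c(576L, 84L, 17L, 0L, 0L, 0L),
                  C4 = c(106L, 105L, 14L, 2L, 0L, 0L))
  sw <- structure(list(counts = counts,
                       deltas = seq(0, 0.5, by = 0.1)),
                  class = "delta_sweep")
  rk <- rank_tightness(sw, min_genes = 7L)
  expect_identical(rk$cluster, c("C1", "C2", "C3", "C4"))
  # C1 outlasts everyone; C2 beats C3/C4 on size at delta 0.2
  expect_equal(rk$max_delta, c(0.5, 0.2, 0.2, 0.2))
  expect_equal(rk$n_at_max, c(79, 47, 17, 14))
  # moderate changes of min_genes leave the top ordering alone
  rk10 <- rank_tightness(sw, min_genes = 10L)
  expect_identical(rk10$cluster[1:2], rk$cluster[1:2])
})

test_that("clusters never reaching min_genes rank last", {
  counts <- cbind(C1 = c(50L, 20L), C2 = c(3L, 0L), C3 = c(9L, 8L))
  sw <- structure(list(counts = counts, deltas = c(0, 0.1)),
                  class = "delta_sweep")
  rk <- rank_tightness(sw, min_genes = 7L)
  expect_identical(rk$cluster, c("C1", "C3", "C2"))
  expect_true(is.na(rk$max_delta[3]))
})

test_that("the selection surface flags Pareto-dominated clusters", {
  report <- list(summary = data.frame(
    delta = c(0, 0, 0),
    cluster = c("C1", "C2", "C3"),
    n_genes = c(100L, 40L, 60L),
    mean_mse = c(0.2, 0.5, 0.1)))
  s <- selection_surface(report)
  expect_true(s$pareto[s$cluster == "C1"])   # most genes
  expect_true(s$pareto[s$cluster == "C3"])   # lowest MSE
  expect_false(s$pareto[s$cluster == "C2"])  # dominated by both
  # single cluster is trivially on the front
  s1 <- selection_surface(list(summary = report$summary[1, ]))
  expect_true(s1$pareto)
})
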
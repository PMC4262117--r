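# Fixtures are built in code; nothing is read from disk.

# dataset wrapper with explicit state tag (content under the test's control)
make_dataset <- function(values, state = "standardized", id = "D1",
                         gene_ids = sprintf("g%03d", seq_len(nrow(values))),
                         conditions = sprintf("c%02d",
                                              seq_len(ncol(values)))) {
  expression_dataset(values, gene_ids, conditions, dataset_id = id,
                     state = state)
}

# population-z-scored rows, so every row has ||x||^2 = N
zscore_rows <- function(m) {
  ctr <- m - rowMeans(m)
  ctr / sqrt(rowMeans(ctr^2))
}

# random column-stochastic CoPaM
random_copam <- function(K, M, level = "final") {
  m <- matrix(stats::rexp(K * M), K, M)
  m <- sweep(m, 2L, colSums(m), "/")
  colnames(m) <- sprintf("g%04d", seq_len(M))
  copam(m, level)
}

# two well-separated gaussian blobs in N dimensions
blob_dataset <- function(n_per = 10L, N = 5L, sep = 10, sd = 0.3,
                         id = "D1") {
  x <- rbind(matrix(stats::rnorm(n_per * N, 0, sd), n_per, N),
             matrix(stats::rnorm(n_per * N, sep, sd), n_per, N))
  make_dataset(x, id = id)
}

# small synthetic collection config for fast unit tests
tiny_config <- function(seed = 7L, ...) {
  args <- list(n_genes = 120L, n_datasets = 4L,
               conditions_range = c(6L, 12L),
               module_sizes = c(24L, 16L),
               n_confounder_modules = 1L, confounder_size = 10L,
               seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# standardized datasets from a generated collection
preprocess_collection <- function(coll) {
  lapply(seq_along(coll$datasets), function(i)
    preprocess_dataset(coll$datasets[[i]], coll$replicate_maps[[i]]))
}

# total within-cluster sum of squares of an assignment vector
wss_of <- function(x, assign) {
  sum(vapply(unique(assign), function(k) {
    xi <- x[assign == k, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }, numeric(1)))
}

# naive per-gene MSE oracle: explicit double loop over genes and conditions
mse_oracle <- function(x_members) {
  N <- ncol(x_members); Mk <- nrow(x_members)
  z <- colMeans(x_members)
  total <- 0
  for (i in seq_len(Mk)) for (j in seq_len(N))
    total <- total + (x_members[i, j] - z[j])^2
  total / (N * Mk)
}

# exhaustive minimum total matched distance over row permutations
optimal_relabel_cost <- function(ref, tgt) {
  K <- nrow(ref)
  perms <- perms_of(K)
  D <- as.matrix(dist(rbind(ref, tgt)))[seq_len(K), K + seq_len(K)]^2
  min(vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]), numeric(1)))
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- perms_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) for (p in sub) {
    rest <- seq_len(n)[-first]
    out[[i <- i + 1L]] <- c(first, rest[p])
  }
  out
}
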
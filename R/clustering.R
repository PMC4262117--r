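#' Construct a hard partition
#'
#' A \code{hard_partition} is a K x M binary membership matrix (rows =
#' clusters, columns = genes) in which every gene column sums to exactly 1.
#' Clusters may be empty (all-zero rows), which happens for unoccupied SOM
#' units.
#'
#' @param membership binary matrix or an integer vector of cluster
#'   assignments (length M, values in 1..K).
#' @param K number of clusters (needed when \code{membership} is a vector
#'   and some clusters are empty).
#' @param gene_ids gene identifiers for the columns.
#' @param method method tag, e.g. \code{"kmeans_ka"}.
#' @param dataset_id dataset the partition was computed on.
#' @return Object of class \code{hard_partition}.
#' @export
hard_partition <- function(membership, K = NULL, gene_ids = NULL,
                           method = "unknown", dataset_id = "D") {
  if (!is.matrix(membership)) {
    assign <- as.integer(membership)
    if (is.null(K)) K <- max(assign)
    m <- matrix(0L, K, length(assign))
    m[cbind(assign, seq_along(assign))] <- 1L
    membership <- m
  }
  if (!all(membership %in% c(0, 1)))
    stop("membership must be binary")
  cs <- colSums(membership)
  if (!all(cs == 1))
    stop("every gene must belong to exactly one cluster; offending columns: ",
         paste(utils::head(which(cs != 1)), collapse = ", "))
  if (is.null(gene_ids)) gene_ids <- colnames(membership)
  if (!is.null(gene_ids)) colnames(membership) <- gene_ids
  rownames(membership) <- paste0("C", seq_len(nrow(membership)))
  structure(list(membership = membership, method = method,
                 dataset_id = dataset_id),
            class = "hard_partition")
}

#' @export
print.hard_partition <- function(x, ...) {
  cat("Hard partition (", x$method, ") on ", x$dataset_id, ": ",
      nrow(x$membership), " clusters x ", ncol(x$membership), " genes\n",
      sep = "")
  invisible(x)
}

.standardized_values <- function(dataset, op) {
  .check_state(dataset, "standardized", op)
  dataset$values
}

#' Kaufman-initialised k-means clustering of gene profiles
#'
#' Deterministic k-means: seeds come from the Kaufman & Rousseeuw build
#' phase (first seed is the most central point; each further seed maximises
#' the summed reduction in every point's distance to its nearest seed),
#' followed by Lloyd iterations on Euclidean distance until the largest
#' centroid shift falls below \code{tol} or \code{max_iter} is reached.
#' A cluster emptied during iteration is reseeded at the currently
#' worst-fitted point (the gene farthest from its assigned centroid).
#' No randomness is involved.
#'
#' @param dataset a standardized \code{expression_dataset}.
#' @param K number of clusters, 2 <= K < number of genes.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence threshold on the maximum centroid displacement.
#' @return A \code{hard_partition} with method tag \code{"kmeans_ka"}.
#' @export
kmeans_ka <- function(dataset, K, max_iter = 300L, tol = 1e-6) {
  x <- .standardized_values(dataset, "kmeans_ka")
  M <- nrow(x)
  if (K < 2L || K >= M) stop("need 2 <= K < number of genes")
  D <- as.matrix(stats::dist(x))
  seeds <- integer(K)
  seeds[1L] <- which.min(rowSums(D))
  # nearest-seed distance for every point
  nearest <- D[, seeds[1L]]
  for (s in seq_len(K)[-1L]) {
    # gain of making i a seed: sum_j max(nearest_j - d(i,j), 0)
    gain <- colSums(pmax(nearest - D, 0))
    gain[seeds[seq_len(s - 1L)]] <- -Inf
    seeds[s] <- which.max(gain)
    nearest <- pmin(nearest, D[, seeds[s]])
  }
  centers <- x[seeds, , drop = FALSE]
  assign <- integer(M)
  for (it in seq_len(max_iter)) {
    d2 <- .dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(assign == k)) {
        worst <- which.max(d2[cbind(seq_len(M), assign)])
        assign[worst] <- k
        message("kmeans_ka: reseeded empty cluster ", k,
                " at gene ", worst)
        d2 <- .dist2_to_centers(x, centers)  # unchanged; assignment patched
      }
    }
    new_centers <- t(vapply(seq_len(K), function(k)
      colMeans(x[assign == k, , drop = FALSE]), numeric(ncol(x))))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  hard_partition(assign, K = K, gene_ids = dataset$gene_ids,
                 method = "kmeans_ka", dataset_id = dataset$dataset_id)
}

# squared Euclidean distances from each row of x to each row of centers
.dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * cross
  pmax(d2, 0)
}

#' Self-organising map clustering with bubble neighbourhood
#'
#' Trains a rows-by-cols SOM on the gene profiles and assigns each gene to
#' its best-matching unit.  The bubble neighbourhood updates every unit
#' within the current (linearly shrinking) radius of the winner by the full
#' learning rate.  Codebooks are initialised from a seeded random sample of
#' gene profiles and the per-epoch presentation order is drawn from the same
#' seed, so runs are reproducible.  Unoccupied units yield empty clusters.
#'
#' @param dataset a standardized \code{expression_dataset}.
#' @param grid integer vector \code{c(rows, cols)}; \code{rows * cols}
#'   clusters are produced.
#' @param seed RNG seed for initialisation and presentation order.
#' @param epochs number of passes over the genes.
#' @param alpha0 initial learning rate (linear decay to zero).
#' @param radius0 initial neighbourhood radius; default half the grid
#'   diagonal.
#' @return A \code{hard_partition} with method tag \code{"som_bubble"}.
#' @export
som_bubble <- function(dataset, grid = c(4L, 4L), seed = 0L,
                       epochs = 500L, alpha0 = 0.5,
                       radius0 = sqrt(sum((grid - 1)^2)) / 2) {
  x <- .standardized_values(dataset, "som_bubble")
  M <- nrow(x)
  K <- prod(grid)
  coords <- expand.grid(gx = seq_len(grid[2L]), gy = seq_len(grid[1L]))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  init <- x[sample.int(M, K, replace = K > M), , drop = FALSE]
  order <- matrix(0L, epochs, M)
  for (e in seq_len(epochs)) order[e, ] <- sample.int(M) - 1L
  codes <- .som_train_cpp(x, init, order, coords$gx, coords$gy,
                          alpha0, radius0)
  assign <- .som_map_cpp(x, codes)
  hard_partition(assign, K = K, gene_ids = dataset$gene_ids,
                 method = "som_bubble", dataset_id = dataset$dataset_id)
}

#' Ward hierarchical clustering cut to K clusters
#'
#' Agglomerative clustering of gene profiles with Ward's minimum-variance
#' linkage on Euclidean distances, cut to exactly \code{K} clusters.
#'
#' @param dataset a standardized \code{expression_dataset}.
#' @param K number of clusters, 1 <= K <= number of genes.
#' @return A \code{hard_partition} with method tag \code{"hc_ward"}.
#' @export
hc_ward <- function(dataset, K) {
  x <- .standardized_values(dataset, "hc_ward")
  if (K < 1L || K > nrow(x)) stop("need 1 <= K <= number of genes")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  assign <- stats::cutree(hc, k = K)
  hard_partition(as.integer(assign), K = K, gene_ids = dataset$gene_ids,
                 method = "hc_ward", dataset_id = dataset$dataset_id)
}

#' Write / read a hard partition as TSV
#'
#' Rows are clusters, columns genes, entries 0/1; method and dataset tags
#' are kept in a leading comment line.
#'
#' @param partition a \code{hard_partition}.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s dataset=%s", partition$method,
                     partition$dataset_id), con)
  writeLines(paste(c("cluster", colnames(partition$membership)),
                   collapse = "\t"), con)
  for (k in seq_len(nrow(partition$membership)))
    writeLines(paste(c(rownames(partition$membership)[k],
                       partition$membership[k, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  lines <- readLines(path)
  tags <- regmatches(lines[1L],
                     regexec("# method=(\\S+) dataset=(\\S+)", lines[1L]))[[1L]]
  body <- utils::read.table(text = lines[-1L], sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
  hard_partition(as.matrix(body), gene_ids = colnames(body),
                 method = tags[2L], dataset_id = tags[3L])
}
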
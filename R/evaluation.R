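#' Per-gene mean squared error of one cluster in one dataset
#'
#' Cluster compactness for z-scored profiles: with N conditions and M_k
#' member genes whose profiles are x_i and whose within-dataset mean
#' profile is z_k,
#' \deqn{MSE = \frac{1}{N M_k} \sum_i \lVert x_i - z_k \rVert^2.}
#' Normalizing per gene makes values comparable across cluster sizes; a
#' singleton cluster scores 0, and a pair of exactly opposite
#' population-z-scored profiles scores 1.
#'
#' @param partition a \code{binarized_partition}.
#' @param dataset a standardized \code{expression_dataset} over the same
#'   genes.
#' @param k cluster index.
#' @return Non-negative number, or \code{NA_real_} for an empty cluster.
#' @export
mse_cluster <- function(partition, dataset, k) {
  x <- .standardized_values(dataset, "mse_cluster")
  members <- which(partition$membership[k, ] == 1)
  if (!length(members)) return(NA_real_)
  xm <- x[members, , drop = FALSE]
  z <- colMeans(xm)
  sum(sweep(xm, 2L, z)^2) / (ncol(x) * length(members))
}

#' MSE report over a delta sweep and all datasets
#'
#' Computes, for every cluster at every delta, the per-dataset MSE and the
#' unweighted average over datasets.  Clusters empty at a delta are absent
#' from the per-dataset table and carry \code{NA} in the summary.
#'
#' @param sweep a \code{delta_sweep}.
#' @param datasets list of standardized \code{expression_dataset} objects.
#' @return A list of class \code{mse_report}: \code{per_dataset}
#'   (long data frame: delta, cluster, dataset_id, n_genes, mse) and
#'   \code{summary} (delta, cluster, n_genes, mean_mse).
#' @export
mse_report <- function(sweep, datasets) {
  if (!length(datasets)) stop("no datasets supplied")
  rows <- list()
  summ <- list()
  for (di in seq_along(sweep$deltas)) {
    p <- sweep$partitions[[di]]
    delta <- sweep$deltas[di]
    sizes <- rowSums(p$membership)
    for (k in seq_len(nrow(p$membership))) {
      cl <- rownames(p$membership)[k]
      if (sizes[k] == 0) {
        summ[[length(summ) + 1L]] <-
          data.frame(delta = delta, cluster = cl, n_genes = 0L,
                     mean_mse = NA_real_)
        next
      }
      vals <- vapply(datasets, function(d) mse_cluster(p, d, k),
                     numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(delta = delta, cluster = cl,
                   dataset_id = vapply(datasets, `[[`, "", "dataset_id"),
                   n_genes = sizes[k], mse = vals, row.names = NULL)
      summ[[length(summ) + 1L]] <-
        data.frame(delta = delta, cluster = cl,
                   n_genes = as.integer(sizes[k]), mean_mse = mean(vals))
    }
  }
  structure(list(per_dataset = do.call(rbind, rows),
                 summary = do.call(rbind, summ)),
            class = "mse_report")
}

#' @export
print.mse_report <- function(x, ...) {
  cat("MSE report:", length(unique(x$summary$cluster)), "clusters x",
      length(unique(x$summary$delta)), "delta values\n")
  print(utils::head(x$summary[!is.na(x$summary$mean_mse), ], 10L))
  invisible(x)
}

#' Rank clusters by tightness
#'
#' A cluster is tighter the higher the delta up to which it retains at
#' least \code{min_genes} genes; clusters reaching the same delta are
#' ordered by the number of genes they hold at that delta (larger first),
#' with a final deterministic tie-break on cluster index.  Clusters that
#' never hold \code{min_genes} genes rank last, ordered by their count at
#' the lowest delta.
#'
#' @param sweep a \code{delta_sweep}.
#' @param min_genes retention threshold (default 7; the ordering is
#'   insensitive to moderate changes of this value).
#' @return Data frame of class \code{tightness_ranking}: rank, cluster,
#'   max_delta (NA if never retaining \code{min_genes}), n_at_max.  The
#'   full retention matrix travels as attribute \code{"counts"}.
#' @export
rank_tightness <- function(sweep, min_genes = 7L) {
  counts <- sweep$counts
  deltas <- sweep$deltas
  K <- ncol(counts)
  max_delta <- rep(NA_real_, K)
  n_at_max <- integer(K)
  for (k in seq_len(K)) {
    ok <- which(counts[, k] >= min_genes)
    if (length(ok)) {
      i <- max(ok)
      max_delta[k] <- deltas[i]
      n_at_max[k] <- counts[i, k]
    } else {
      n_at_max[k] <- counts[1L, k]
    }
  }
  key_delta <- ifelse(is.na(max_delta), -Inf, max_delta)
  ord <- order(-key_delta, -n_at_max, seq_len(K))
  out <- data.frame(rank = seq_len(K),
                    cluster = colnames(counts)[ord],
                    max_delta = max_delta[ord],
                    n_at_max = n_at_max[ord])
  attr(out, "counts") <- counts
  attr(out, "min_genes") <- min_genes
  class(out) <- c("tightness_ranking", "data.frame")
  out
}

#' Gene-count / MSE selection surface with Pareto flags
#'
#' Good clusters minimise MSE while maximising size; rather than picking
#' winners automatically, this reports, per delta, which non-empty
#' clusters are Pareto-optimal in (more genes, lower mean MSE).
#'
#' @param report an \code{mse_report}.
#' @return Data frame: delta, cluster, n_genes, mean_mse, pareto (logical).
#' @export
selection_surface <- function(report) {
  s <- report$summary[report$summary$n_genes > 0, , drop = FALSE]
  s$pareto <- FALSE
  for (d in unique(s$delta)) {
    idx <- which(s$delta == d)
    for (i in idx) {
      dominated <- any(s$n_genes[idx] >= s$n_genes[i] &
                       s$mean_mse[idx] <= s$mean_mse[i] &
                       (s$n_genes[idx] > s$n_genes[i] |
                        s$mean_mse[idx] < s$mean_mse[i]))
      s$pareto[i] <- !dominated
    }
  }
  rownames(s) <- NULL
  s
}

#' Closed-form co-expression link arithmetic
#'
#' For a module of \code{n_genes} genes validated against a co-expression
#' network: the number of possible undirected links is
#' \code{choose(n_genes, 2)}; the observed link count is expressed as a
#' percentage of that, and, given a null mean and standard deviation of
#' link counts for random gene sets of the same size, as a normal-tail
#' probability.
#'
#' @param n_genes module size.
#' @param observed_links observed co-expression links.
#' @param null_mean,null_sd optional null-distribution moments from random
#'   gene sets.
#' @return List: \code{possible_links}, \code{percent}, and (when a null
#'   is given) \code{z} and \code{p_value}.
#' @export
coexpression_link_stats <- function(n_genes, observed_links,
                                    null_mean = NULL, null_sd = NULL) {
  possible <- choose(n_genes, 2)
  if (observed_links > possible)
    stop("observed links exceed the possible ", possible)
  out <- list(possible_links = possible,
              percent = 100 * observed_links / possible)
  if (!is.null(null_mean) && !is.null(null_sd)) {
    out$z <- (observed_links - null_mean) / null_sd
    out$p_value <- stats::pnorm(observed_links, null_mean, null_sd,
                                lower.tail = FALSE)
  }
  out
}
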
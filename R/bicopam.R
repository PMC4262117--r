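#' Fit a Bi-CoPaM consensus clustering across datasets
#'
#' The central estimator of the package.  Each standardized dataset is
#' clustered independently by the configured methods; per dataset the
#' resulting hard partitions are min-min relabelled, averaged into an
#' intermediate consensus partition matrix (CoPaM), and pushed towards
#' binary memberships; the per-dataset CoPaMs are then fused into the
#' final CoPaM, which is binarized by difference-threshold binarization
#' over the delta grid.  Clusters are scored by the per-gene MSE averaged
#' over datasets and ranked by tightness (the highest delta at which a
#' cluster still retains \code{min_genes} genes, then size).
#'
#' @param datasets list of \code{expression_dataset} objects in state
#'   \code{"standardized"}, sharing one ordered gene universe.  The list
#'   order is the fusion order (greedy relabeling makes the consensus
#'   mildly order-dependent) and is recorded in the result.
#' @param K number of clusters (default 16).
#' @param methods subset of \code{c("kmeans_ka", "som_bubble",
#'   "hc_ward")}.
#' @param deltas ascending delta grid for the sweep.
#' @param min_genes retention threshold for the tightness ranking.
#' @param som_grid SOM grid \code{c(rows, cols)}; default the most nearly
#'   square factorization of \code{K}.
#' @param som_seed seed for SOM initialisation and presentation order.
#' @param relabel_method \code{"greedy"} min-min (default) or
#'   \code{"optimal"} exhaustive assignment (K <= 8).
#' @return Object of class \code{bicopam} with elements \code{copam}
#'   (final CoPaM), \code{sweep} (\code{delta_sweep}), \code{counts},
#'   \code{mse} (\code{mse_report}), \code{tightness}
#'   (\code{tightness_ranking}), \code{surface} (Pareto selection
#'   surface), \code{partitions} (per dataset, per method), the
#'   configuration, and \code{call}.
#' @seealso \code{\link{antiphase_summary}} for screening cluster pairs,
#'   \code{\link{score_recovery}} for benchmarking against planted
#'   modules.
#' @export
bicopam <- function(datasets, K = 16L,
                    methods = c("kmeans_ka", "som_bubble", "hc_ward"),
                    deltas = seq(0, 1, by = 0.1),
                    min_genes = 7L,
                    som_grid = NULL,
                    som_seed = 0L,
                    relabel_method = c("greedy", "optimal")) {
  cl <- match.call()
  relabel_method <- match.arg(relabel_method)
  methods <- match.arg(methods, c("kmeans_ka", "som_bubble", "hc_ward"),
                       several.ok = TRUE)
  if (!length(datasets)) stop("no datasets supplied")
  for (d in datasets) .check_state(d, "standardized", "bicopam")
  universe <- datasets[[1L]]$gene_ids
  for (d in datasets[-1L])
    if (!identical(d$gene_ids, universe))
      stop("dataset ", d$dataset_id,
           " is not aligned to the common gene universe; ",
           "run align_gene_universe() first")
  if (is.null(som_grid)) som_grid <- .square_grid(K)
  if (prod(som_grid) != K) stop("som_grid must multiply to K")
  partitions <- vector("list", length(datasets))
  intermediates <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    ps <- lapply(methods, function(m) switch(m,
      kmeans_ka  = kmeans_ka(d, K),
      som_bubble = som_bubble(d, grid = som_grid, seed = som_seed),
      hc_ward    = hc_ward(d, K)))
    names(ps) <- methods
    partitions[[i]] <- ps
    intermediates[[i]] <-
      push_memberships(build_intermediate_copam(ps, relabel_method))
  }
  names(partitions) <- vapply(datasets, `[[`, "", "dataset_id")
  final <- build_final_copam(intermediates, relabel_method)
  sweep <- delta_sweep(final, deltas)
  mse <- mse_report(sweep, datasets)
  tight <- rank_tightness(sweep, min_genes)
  structure(list(copam = final,
                 sweep = sweep,
                 counts = sweep$counts,
                 mse = mse,
                 tightness = tight,
                 surface = selection_surface(mse),
                 partitions = partitions,
                 K = K, methods = methods, deltas = deltas,
                 min_genes = min_genes, som_grid = som_grid,
                 som_seed = som_seed, relabel_method = relabel_method,
                 dataset_ids = names(partitions),
                 gene_ids = universe,
                 call = cl),
            class = "bicopam")
}

.square_grid <- function(K) {
  r <- floor(sqrt(K))
  while (K %% r != 0L) r <- r - 1L
  c(r, K %/% r)
}

#' @export
print.bicopam <- function(x, ...) {
  cat("Bi-CoPaM consensus clustering\n")
  cat("  ", length(x$dataset_ids), " datasets, ", length(x$gene_ids),
      " genes, K = ", x$K, ", methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  top <- utils::head(x$tightness, 3L)
  cat("  tightest clusters: ",
      paste(sprintf("%s (delta<=%s, %d genes)", top$cluster,
                    format(top$max_delta), top$n_at_max),
            collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bicopam <- function(object, ...) {
  structure(list(tightness = object$tightness,
                 counts = object$counts,
                 surface = object$surface,
                 K = object$K,
                 dataset_ids = object$dataset_ids),
            class = "summary.bicopam")
}

#' @export
print.summary.bicopam <- function(x, ...) {
  cat("Gene counts per cluster over the delta sweep:\n")
  print(x$counts)
  cat("\nTightness ranking (min_genes = ",
      attr(x$tightness, "min_genes"), "):\n", sep = "")
  print(as.data.frame(x$tightness), row.names = FALSE)
  invisible(x)
}

#' Plot a fitted consensus clustering
#'
#' Two panels in the style of the classic tightness-sweep figures: mean
#' per-gene MSE versus delta and retained gene count versus delta, one
#' line per cluster (restricted to the tightest \code{top} clusters).
#' Empty clusters leave gaps.
#'
#' @param x a \code{bicopam} object.
#' @param top number of top-ranked clusters to draw.
#' @param ... ignored.
#' @export
plot.bicopam <- function(x, top = 6L, ...) {
  keep <- utils::head(x$tightness$cluster, top)
  s <- x$mse$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(keep), "Dark 3")
  graphics::plot(NA, xlim = range(x$deltas),
                 ylim = range(s$mean_mse, na.rm = TRUE),
                 xlab = expression(delta), ylab = "mean per-gene MSE",
                 main = "Cluster compactness")
  for (i in seq_along(keep)) {
    si <- s[s$cluster == keep[i], ]
    graphics::lines(si$delta, si$mean_mse, col = cols[i], type = "b",
                    pch = 16)
  }
  graphics::plot(NA, xlim = range(x$deltas),
                 ylim = c(0, max(x$counts[, keep, drop = FALSE])),
                 xlab = expression(delta), ylab = "genes retained",
                 main = "Cluster size")
  for (i in seq_along(keep))
    graphics::lines(x$deltas, x$counts[, keep[i]], col = cols[i],
                    type = "b", pch = 16)
  graphics::legend("topright", legend = keep, col = cols, lty = 1,
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Extract a binarized membership at a given delta
#'
#' @param fit a \code{bicopam} object.
#' @param delta one of the fitted delta grid values.
#' @return The \code{binarized_partition} at that delta.
#' @export
membership_at <- function(fit, delta) {
  i <- which(abs(fit$deltas - delta) < 1e-9)
  if (!length(i)) stop("delta ", delta, " is not on the fitted grid")
  fit$sweep$partitions[[i]]
}

#' Robustness of the top cluster to the choice of K
#'
#' Refits the consensus for each K and compares the gene set of the
#' top-ranked (tightest) cluster across K values by pairwise Jaccard
#' index.  Gene sets are taken at one common \code{compare_delta} so the
#' comparison is between clusters of commensurate tightness rather than
#' between cores of different sizes.
#'
#' @param datasets list of standardized \code{expression_dataset}s.
#' @param K_values at least two K values.
#' @param compare_delta delta at which the top cluster's gene set is
#'   extracted for the cross-K comparison.
#' @param ... further arguments to \code{\link{bicopam}}.
#' @return Object of class \code{ksweep}: \code{fits} (per K),
#'   \code{top_genes} (per K), \code{jaccard} (pairwise matrix).
#' @export
bicopam_ksweep <- function(datasets, K_values, compare_delta = 0.3, ...) {
  if (length(K_values) < 2L) stop("supply at least two K values")
  fits <- lapply(K_values, function(K) bicopam(datasets, K = K, ...))
  names(fits) <- paste0("K", K_values)
  top_genes <- lapply(fits, function(f) {
    t1 <- f$tightness[1L, ]
    p <- membership_at(f, compare_delta)
    k <- match(t1$cluster, rownames(p$membership))
    colnames(p$membership)[p$membership[k, ] == 1]
  })
  n <- length(fits)
  jac <- matrix(1, n, n, dimnames = list(names(fits), names(fits)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    jac[i, j] <- jac[j, i] <-
      length(intersect(top_genes[[i]], top_genes[[j]])) /
      length(union(top_genes[[i]], top_genes[[j]]))
  }
  structure(list(fits = fits, top_genes = top_genes, jaccard = jac,
                 K_values = K_values),
            class = "ksweep")
}

#' @export
print.ksweep <- function(x, ...) {
  cat("Top-cluster robustness across K =",
      paste(x$K_values, collapse = ", "), "\n")
  cat("Pairwise Jaccard of the top cluster's gene set:\n")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Run the full pipeline from files to a results directory
#'
#' Reads the expression matrices, replicate maps and gene universe named
#' in the configuration, preprocesses each dataset (quantile
#' normalization, median replicate summarization, z-scoring), fits
#' \code{\link{bicopam}}, and writes all quantitative outputs as TSV:
#' per-delta memberships, the gene-count sweep table, the MSE report,
#' the tightness ranking, the Pareto selection surface, an anti-phase
#' summary for the two tightest clusters, and a manifest that makes the
#' run reproducible.
#'
#' @param config list (or path to a flat \code{key = value} text file)
#'   with entries \code{dataset_paths}, optional \code{replicate_maps}
#'   (paths, \code{NA} for none), \code{gene_universe} (path or character
#'   vector), \code{out_dir}, and optional \code{K}, \code{methods},
#'   \code{deltas}, \code{min_genes}, \code{som_seed},
#'   \code{thresholds}.
#' @return The output directory, invisibly; the fitted \code{bicopam}
#'   object is attached as attribute \code{"fit"}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- .read_flat_config(config)
  defaults <- list(K = 16L, methods = c("kmeans_ka", "som_bubble",
                                        "hc_ward"),
                   deltas = seq(0, 1, by = 0.1), min_genes = 7L,
                   som_seed = 0L, thresholds = c(-0.75, -0.7, -0.6))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  datasets <- vector("list", length(config$dataset_paths))
  for (i in seq_along(config$dataset_paths)) {
    d <- read_expression_matrix(config$dataset_paths[i])
    map <- NULL
    mp <- config$replicate_maps[i]
    if (!is.null(mp) && !is.na(mp)) map <- read_replicate_map(mp)
    d <- preprocess_dataset(d, map)
    log <- c(log, attr(d, "log"))
    datasets[[i]] <- d
  }
  universe <- config$gene_universe
  if (length(universe) == 1L && file.exists(universe))
    universe <- read_gene_list(universe)
  aligned <- align_gene_universe(datasets, universe)
  fit <- bicopam(aligned$datasets, K = config$K,
                 methods = config$methods, deltas = config$deltas,
                 min_genes = config$min_genes,
                 som_seed = config$som_seed)
  write_membership_table(fit$sweep, file.path(out, "memberships.tsv"))
  utils::write.table(data.frame(delta = rownames(fit$counts),
                                fit$counts, check.names = FALSE),
                     file.path(out, "cluster_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$mse$per_dataset,
                     file.path(out, "mse_per_dataset.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$mse$summary, file.path(out, "mse_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fit$tightness),
                     file.path(out, "tightness_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$surface, file.path(out, "selection_surface.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_copam(fit$copam, file.path(out, "final_copam.tsv"))
  # anti-phase screen of the two tightest clusters, each at its own
  # maximal retaining delta
  t12 <- fit$tightness[1:2, ]
  if (!any(is.na(t12$max_delta))) {
    p1 <- membership_at(fit, t12$max_delta[1L])
    p2 <- membership_at(fit, t12$max_delta[2L])
    ap <- antiphase_summary(p1,
                            match(t12$cluster[1L],
                                  rownames(p1$membership)),
                            p2,
                            match(t12$cluster[2L],
                                  rownames(p2$membership)),
                            aligned$datasets,
                            thresholds = config$thresholds)
    utils::write.table(ap$per_dataset,
                       file.path(out, "antiphase_per_dataset.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("pair\t%s\t%s", ap$pair[1L], ap$pair[2L]),
                 sprintf("%s\t%d\t%d", names(ap$counts), ap$counts,
                         ap$n_datasets),
                 sprintf("outliers\t%s",
                         paste(ap$outliers, collapse = ","))),
               file.path(out, "antiphase_counts.tsv"))
  }
  manifest <- c(
    sprintf("K\t%d", config$K),
    sprintf("methods\t%s", paste(config$methods, collapse = ",")),
    sprintf("deltas\t%s", paste(config$deltas, collapse = ",")),
    sprintf("min_genes\t%d", config$min_genes),
    sprintf("som_seed\t%d", config$som_seed),
    sprintf("dataset_order\t%s",
            paste(fit$dataset_ids, collapse = ",")),
    sprintf("n_genes\t%d", length(fit$gene_ids)),
    log)
  writeLines(manifest, file.path(out, "manifest.txt"))
  attr(out, "fit") <- fit
  invisible(out)
}

.read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  config <- list()
  for (p in kv) {
    key <- trimws(p[1L])
    val <- trimws(paste(p[-1L], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    config[[key]] <- if (!anyNA(num)) num else vals
  }
  for (nm in c("K", "min_genes", "som_seed"))
    if (!is.null(config[[nm]])) config[[nm]] <- as.integer(config[[nm]])
  config
}
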
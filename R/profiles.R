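#' Per-dataset average expression profile of one cluster
#'
#' The unweighted mean of the member genes' standardized profiles in one
#' dataset; \code{NULL} for an empty cluster.
#'
#' @param partition a \code{binarized_partition}.
#' @param dataset a standardized \code{expression_dataset}.
#' @param k cluster index.
#' @return Numeric vector of length N (the dataset's conditions), or
#'   \code{NULL}.
#' @export
cluster_profile <- function(partition, dataset, k) {
  x <- .standardized_values(dataset, "cluster_profile")
  members <- which(partition$membership[k, ] == 1)
  if (!length(members)) return(NULL)
  colMeans(x[members, , drop = FALSE])
}

#' Average expression profiles of all clusters in all datasets
#'
#' @param partition a \code{binarized_partition}.
#' @param datasets list of standardized \code{expression_dataset} objects.
#' @return Nested list: \code{profiles[[dataset_id]][[cluster]]} holds the
#'   length-N mean profile; empty clusters are omitted.
#' @export
cluster_profiles <- function(partition, datasets) {
  out <- lapply(datasets, function(d) {
    pr <- lapply(seq_len(nrow(partition$membership)),
                 function(k) cluster_profile(partition, d, k))
    names(pr) <- rownames(partition$membership)
    pr[!vapply(pr, is.null, logical(1))]
  })
  names(out) <- vapply(datasets, `[[`, "", "dataset_id")
  out
}

#' Best lead/lag offset between two profiles
#'
#' Slides one profile against the other over integer lags in
#' [-\code{max_lag}, \code{max_lag}] and returns the lag maximising the
#' absolute Pearson correlation of the overlapping segments.  Positive
#' lags mean the second profile lags the first; 0 means the profiles are
#' synchronous.  Ties prefer the smallest \code{|lag|}, then the negative
#' lag, keeping \code{lead_lag(a, b) == -lead_lag(b, a)} whenever the
#' maximum is unique.
#'
#' @param p1,p2 numeric vectors of equal length (ordered time points).
#' @param max_lag maximum offset; must satisfy \code{max_lag < N / 2}.
#' @return Integer lag.
#' @export
lead_lag <- function(p1, p2, max_lag = floor(length(p1) / 4)) {
  n <- length(p1)
  if (length(p2) != n) stop("profiles differ in length")
  if (max_lag >= n / 2) stop("max_lag must be below N / 2")
  lags <- seq.int(-max_lag, max_lag)
  score <- vapply(lags, function(l) {
    if (l >= 0) { a <- p1[seq_len(n - l)]; b <- p2[seq_len(n - l) + l] }
    else        { a <- p1[seq_len(n + l) - l]; b <- p2[seq_len(n + l)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    abs(stats::cor(a, b))
  }, numeric(1))
  best <- max(score)
  cand <- lags[score >= best - 1e-12]
  cand[order(abs(cand), cand)][1L]
}

#' Quantify anti-phase behaviour of a cluster pair across datasets
#'
#' Computes, in every dataset, the Pearson correlation between the two
#' clusters' average profiles, counts datasets falling below each
#' threshold of a configured set, flags datasets whose correlation stays
#' above the weakest threshold (outliers), and reports the best lead/lag
#' offset per dataset.  The two memberships may come from different
#' binarizations (e.g. different delta per cluster).
#'
#' @param partition1,partition2 \code{binarized_partition} objects holding
#'   the two clusters (may be the same object).
#' @param k1,k2 cluster indices within \code{partition1} /
#'   \code{partition2}.
#' @param datasets list of standardized \code{expression_dataset} objects.
#' @param thresholds descending-magnitude negative thresholds for the
#'   exceedance counts.
#' @param max_lag per-dataset lag search bound; default
#'   \code{floor(N / 4)} per dataset.  \code{NA} skips lag analysis (for
#'   collections whose conditions are unordered).
#' @return Object of class \code{antiphase_summary}: data frame
#'   \code{per_dataset} (dataset_id, r, lag), vector \code{counts} (one
#'   per threshold), \code{n_datasets} used, \code{outliers}.
#' @export
antiphase_summary <- function(partition1, k1, partition2, k2, datasets,
                              thresholds = c(-0.75, -0.7, -0.6),
                              max_lag = NULL) {
  rs <- rep(NA_real_, length(datasets))
  lag <- rep(NA_integer_, length(datasets))
  ids <- vapply(datasets, `[[`, "", "dataset_id")
  for (i in seq_along(datasets)) {
    p1 <- cluster_profile(partition1, datasets[[i]], k1)
    p2 <- cluster_profile(partition2, datasets[[i]], k2)
    if (is.null(p1) || is.null(p2))
      stop("cluster empty in dataset ", ids[i])
    n <- length(p1)
    if (n >= 3 && stats::sd(p1) > 0 && stats::sd(p2) > 0)
      rs[i] <- stats::cor(p1, p2)
    ml <- if (is.null(max_lag)) floor(n / 4) else max_lag
    if (!is.na(ml) && ml >= 1 && ml < n / 2)
      lag[i] <- lead_lag(p1, p2, ml)
  }
  usable <- !is.na(rs)
  counts <- vapply(thresholds, function(th) sum(rs[usable] < th),
                   integer(1))
  names(counts) <- paste0("r<", format(thresholds))
  weakest <- max(thresholds)
  structure(list(per_dataset = data.frame(dataset_id = ids, r = rs,
                                          lag = lag),
                 counts = counts,
                 n_datasets = sum(usable),
                 thresholds = thresholds,
                 outliers = ids[usable & rs >= weakest],
                 pair = c(rownames(partition1$membership)[k1],
                          rownames(partition2$membership)[k2])),
            class = "antiphase_summary")
}

#' @export
print.antiphase_summary <- function(x, ...) {
  cat("Anti-phase summary for clusters ", x$pair[1L], " vs ", x$pair[2L],
      " over ", x$n_datasets, " datasets\n", sep = "")
  for (i in seq_along(x$thresholds))
    cat(sprintf("  r < %5.2f in %d/%d datasets\n", x$thresholds[i],
                x$counts[i], x$n_datasets))
  lags <- x$per_dataset$lag
  if (any(!is.na(lags)))
    cat("  modal lead/lag: ", .modal_lag(lags), "\n", sep = "")
  if (length(x$outliers))
    cat("  weak-correlation outliers: ",
        paste(x$outliers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.modal_lag <- function(lags) {
  lags <- lags[!is.na(lags)]
  tab <- table(lags)
  as.integer(names(tab)[which.max(tab)])
}

#' Modal lead/lag over datasets
#'
#' @param x an \code{antiphase_summary}.
#' @return The most frequent per-dataset lag (ties to the first).
#' @export
modal_lag <- function(x) .modal_lag(x$per_dataset$lag)
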
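#' Construct a binarized partition
#'
#' Result of binarizing a CoPaM: a K x M binary matrix whose gene columns
#' sum to 0 (unassigned) or 1, tagged with the technique and, for DTB, the
#' tightness parameter delta.
#'
#' @param membership binary K x M matrix.
#' @param technique \code{"MVB"}, \code{"DTB"} or \code{"IB"}.
#' @param delta the DTB parameter in [0, 1] (0 for MVB, 1 for IB).
#' @return Object of class \code{binarized_partition}.
#' @export
binarized_partition <- function(membership, technique, delta) {
  technique <- match.arg(technique, c("MVB", "DTB", "IB"))
  cs <- colSums(membership)
  if (!all(cs %in% c(0, 1)))
    stop("gene columns must sum to 0 or 1")
  if (technique == "MVB" && any(cs == 0))
    stop("MVB partitions may not contain unassigned genes")
  if (is.null(rownames(membership)))
    rownames(membership) <- paste0("C", seq_len(nrow(membership)))
  structure(list(membership = membership, technique = technique,
                 delta = delta),
            class = "binarized_partition")
}

#' @export
print.binarized_partition <- function(x, ...) {
  cat("Binarized partition [", x$technique,
      if (x$technique == "DTB") paste0(", delta=", format(x$delta)),
      "]: ", sum(colSums(x$membership) == 1), "/", ncol(x$membership),
      " genes assigned over ", nrow(x$membership), " clusters\n", sep = "")
  invisible(x)
}

.top_two <- function(m) {
  # per column: value and index of the largest entry (ties -> lowest row)
  # and value of the runner-up
  top_idx <- max.col(t(m), ties.method = "first")
  top_val <- m[cbind(top_idx, seq_len(ncol(m)))]
  m2 <- m
  m2[cbind(top_idx, seq_len(ncol(m)))] <- -Inf
  second_val <- do.call(pmax, asplit(m2, 1L))
  list(idx = top_idx, top = top_val, second = second_val)
}

#' Maximum value binarization (MVB)
#'
#' Assigns every gene to the cluster in which it has its maximum fuzzy
#' membership, producing complementary clusters with no unassigned genes.
#' Exact ties go to the lowest cluster index and the tied genes are
#' reported in the \code{"ties"} attribute.
#'
#' @param x a final-level \code{copam}.
#' @return A \code{binarized_partition} with technique \code{"MVB"}.
#' @export
binarize_mvb <- function(x) {
  m <- x$membership
  tt <- .top_two(m)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  out[cbind(tt$idx, seq_len(ncol(m)))] <- 1L
  p <- binarized_partition(out, "MVB", 0)
  ties <- colnames(m)[tt$second == tt$top]
  if (length(ties))
    message("binarize_mvb: max-membership ties broken to lowest cluster ",
            "index for: ", paste(ties, collapse = ", "))
  attr(p, "ties") <- ties
  p
}

#' Difference threshold binarization (DTB)
#'
#' A gene is assigned to its maximum-membership cluster only when the
#' runner-up membership is lower than the maximum by at least \code{delta};
#' otherwise the gene is unassigned (all-zero column).  \code{delta = 0}
#' reproduces MVB (ties to the lowest cluster index); \code{delta = 1}
#' keeps exactly the unanimously assigned (binary-column) genes, i.e.
#' intersection binarization.
#'
#' @param x a final-level \code{copam}.
#' @param delta tightness parameter in [0, 1].
#' @return A \code{binarized_partition} with technique \code{"DTB"}.
#' @export
binarize_dtb <- function(x, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  m <- x$membership
  tt <- .top_two(m)
  gap <- tt$top - tt$second
  assigned <- gap >= delta - 1e-12
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  w <- which(assigned)
  out[cbind(tt$idx[w], w)] <- 1L
  binarized_partition(out, "DTB", delta)
}

#' Intersection binarization (IB)
#'
#' Retains only genes assigned to one cluster by every contributing
#' partition, i.e. genes whose consensus column is already binary.
#' Definitionally equal to \code{binarize_dtb(x, 1)}.
#'
#' @param x a final-level \code{copam}.
#' @return A \code{binarized_partition} with technique \code{"IB"}.
#' @export
binarize_ib <- function(x) {
  p <- binarize_dtb(x, 1)
  p$technique <- "IB"
  p
}

#' Binarize a CoPaM over a grid of delta values
#'
#' Runs DTB at every delta of an ascending grid and tabulates the
#' per-cluster gene counts, reproducing the classic
#' tightness-sweep summary table (rows = delta from complementary 0 to
#' tightest 1, columns = clusters).
#'
#' @param x a final-level \code{copam}.
#' @param deltas ascending numeric vector in [0, 1].
#' @return A list of class \code{delta_sweep} with elements
#'   \code{partitions} (named by delta), \code{counts} (deltas x clusters
#'   gene-count matrix) and \code{deltas}.
#' @export
delta_sweep <- function(x, deltas = seq(0, 1, by = 0.1)) {
  if (is.unsorted(deltas)) stop("deltas must be ascending")
  partitions <- lapply(deltas, function(d) binarize_dtb(x, d))
  names(partitions) <- format(deltas)
  counts <- t(vapply(partitions, function(p) rowSums(p$membership),
                     numeric(nrow(x$membership))))
  rownames(counts) <- format(deltas)
  structure(list(partitions = partitions, counts = counts,
                 deltas = deltas),
            class = "delta_sweep")
}

#' @export
print.delta_sweep <- function(x, ...) {
  cat("DTB delta sweep over", length(x$deltas), "delta values\n")
  print(x$counts)
  invisible(x)
}

#' Write per-delta cluster memberships as a gene table
#'
#' One row per gene, one column per delta holding the assigned cluster
#' label or \code{"-"} for unassigned.
#'
#' @param sweep a \code{delta_sweep} (or list of
#'   \code{binarized_partition} objects named by delta).
#' @param path output file path.
#' @export
write_membership_table <- function(sweep, path) {
  partitions <- if (inherits(sweep, "delta_sweep")) sweep$partitions
                else sweep
  genes <- colnames(partitions[[1L]]$membership)
  cols <- vapply(partitions, function(p) {
    m <- p$membership
    lab <- rep("-", ncol(m))
    assigned <- colSums(m) == 1
    lab[assigned] <- rownames(m)[max.col(t(m[, assigned, drop = FALSE]),
                                         ties.method = "first")]
    lab
  }, character(length(genes)))
  df <- data.frame(gene = genes, cols, check.names = FALSE)
  names(df) <- c("gene", paste0("delta_", names(partitions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a per-delta membership table
#'
#' @param path file written by \code{\link{write_membership_table}}.
#' @return data frame, one row per gene, cluster label or \code{"-"} per
#'   delta column.
#' @export
read_membership_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
}
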
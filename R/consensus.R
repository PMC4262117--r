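#' Construct a consensus partition matrix (CoPaM)
#'
#' A CoPaM is a K x M matrix of fuzzy membership values in [0, 1] whose
#' gene columns each sum to 1.  \code{level} records whether it fuses the
#' clustering methods of a single dataset (\code{"intermediate"}) or all
#' datasets (\code{"final"}).
#'
#' @param membership numeric K x M matrix.
#' @param level \code{"intermediate"} or \code{"final"}.
#' @param provenance character vector of contributing partition tags.
#' @return Object of class \code{copam}.
#' @export
copam <- function(membership, level = c("intermediate", "final"),
                  provenance = character()) {
  level <- match.arg(level)
  membership <- as.matrix(membership)
  if (any(membership < -1e-12) || any(membership > 1 + 1e-12))
    stop("membership values must lie in [0, 1]")
  cs <- colSums(membership)
  if (any(abs(cs - 1) > 1e-9))
    stop("every gene column must sum to 1; worst deviation ",
         format(max(abs(cs - 1))))
  if (is.null(rownames(membership)))
    rownames(membership) <- paste0("C", seq_len(nrow(membership)))
  structure(list(membership = membership, level = level,
                 provenance = provenance),
            class = "copam")
}

#' @export
print.copam <- function(x, ...) {
  nz <- mean(colSums(x$membership > 0))
  cat("CoPaM (", x$level, "): ", nrow(x$membership), " clusters x ",
      ncol(x$membership), " genes; mean column support ",
      format(nz, digits = 3), "\n", sep = "")
  invisible(x)
}

.membership_of <- function(x) {
  if (inherits(x, c("hard_partition", "copam"))) x$membership
  else as.matrix(x)
}

#' Relabel a partition against a reference by min-min matching
#'
#' Cluster labels produced by independent clusterings are arbitrary; before
#' averaging, each target cluster row must be matched to the reference row
#' it corresponds to.  The greedy min-min scheme repeatedly fixes the
#' globally closest (reference row, target row) pair under Euclidean
#' distance between membership vectors, removes both, and repeats; ties are
#' broken towards the lowest (reference index, target index).  An exhaustive
#' optimal-assignment mode is available for sensitivity analysis
#' (feasible for K <= 8).
#'
#' @param reference a \code{copam}, \code{hard_partition}, or membership
#'   matrix serving as the label reference.
#' @param target a \code{hard_partition} (or \code{copam}) to relabel.
#' @param method \code{"greedy"} (min-min) or \code{"optimal"}
#'   (minimum total distance over all row permutations).
#' @return \code{target} with its rows permuted into reference order.
#' @export
relabel_min_min <- function(target, reference,
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  ref <- .membership_of(reference)
  tgt <- .membership_of(target)
  if (!all(dim(ref) == dim(tgt)))
    stop("reference and target have different shapes: ",
         paste(dim(ref), collapse = "x"), " vs ",
         paste(dim(tgt), collapse = "x"))
  K <- nrow(ref)
  D <- .dist2_to_centers(ref, tgt)  # K x K squared distances
  perm <- integer(K)                # perm[i] = target row matched to ref row i
  if (method == "greedy") {
    Dw <- D
    for (step in seq_len(K)) {
      # which.min scans column-major: lowest column (target) index wins ties,
      # and within a column the lowest reference index — matching the
      # (reference index, target index) tie rule after the transpose below.
      idx <- arrayInd(which.min(t(Dw)), dim(Dw))
      i <- idx[2L]; j <- idx[1L]
      perm[i] <- j
      Dw[i, ] <- Inf
      Dw[, j] <- Inf
    }
  } else {
    if (K > 8L) stop("optimal assignment is exhaustive; K <= 8 required")
    perms <- .permutations(K)
    costs <- vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]),
                    numeric(1))
    perm <- perms[[which.min(costs)]]
  }
  out <- tgt[perm, , drop = FALSE]
  rownames(out) <- rownames(ref)
  if (inherits(target, "hard_partition"))
    hard_partition(out, gene_ids = colnames(out), method = target$method,
                   dataset_id = target$dataset_id)
  else if (inherits(target, "copam"))
    copam(out, target$level, target$provenance)
  else out
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) for (p in sub) {
    rest <- seq_len(n)[-first]
    out[[i <- i + 1L]] <- c(first, rest[p])
  }
  out
}

.partition_tag <- function(p) paste0(p$dataset_id, ":", p$method)

#' Fuse one dataset's partitions into an intermediate CoPaM
#'
#' The first partition serves as the initial consensus; every subsequent
#' partition is min-min relabelled against the running element-wise
#' average and then averaged in with equal weight.
#'
#' @param partitions list of \code{hard_partition} objects over the same
#'   genes (typically the three clustering methods on one dataset).
#' @param relabel_method passed to \code{\link{relabel_min_min}}.
#' @return A \code{copam} with level \code{"intermediate"}.
#' @export
build_intermediate_copam <- function(partitions,
                                     relabel_method = "greedy") {
  if (!length(partitions)) stop("no partitions supplied")
  avg <- .membership_of(partitions[[1L]]) * 1.0
  for (t in seq_along(partitions)[-1L]) {
    rel <- relabel_min_min(partitions[[t]], avg, method = relabel_method)
    avg <- avg * ((t - 1) / t) + .membership_of(rel) / t
  }
  copam(avg, "intermediate",
        provenance = vapply(partitions, .partition_tag, character(1)))
}

#' Push CoPaM memberships towards binary values
#'
#' For each gene, memberships below the mean of its nonzero memberships
#' are set to zero and the survivors are renormalized to sum 1.  Binary
#' columns are fixed points; a column can never gain support.
#'
#' @param x a \code{copam} (normally level \code{"intermediate"}).
#' @return The pushed \code{copam}.
#' @export
push_memberships <- function(x) {
  m <- x$membership
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    mj <- mean(col[col > 0])
    col[col < mj] <- 0
    m[, j] <- col / sum(col)
  }
  copam(m, x$level, x$provenance)
}

#' Fuse per-dataset CoPaMs into the final CoPaM
#'
#' Sequential min-min relabeling of each (pushed) intermediate CoPaM
#' against the running element-wise average, with equal weight for every
#' dataset.  The dataset order is the list order; greedy relabeling makes
#' the result order-dependent, so callers should fix and record it.
#'
#' @param intermediates list of pushed intermediate \code{copam} objects,
#'   one per dataset, same shape.
#' @param relabel_method passed to \code{\link{relabel_min_min}}.
#' @return A \code{copam} with level \code{"final"}.
#' @export
build_final_copam <- function(intermediates, relabel_method = "greedy") {
  if (!length(intermediates)) stop("no intermediate CoPaMs supplied")
  avg <- .membership_of(intermediates[[1L]])
  for (t in seq_along(intermediates)[-1L]) {
    rel <- relabel_min_min(intermediates[[t]], avg,
                           method = relabel_method)
    avg <- avg * ((t - 1) / t) + .membership_of(rel) / t
  }
  copam(avg, "final",
        provenance = unlist(lapply(intermediates, `[[`, "provenance")))
}

#' Write / read a CoPaM as TSV
#'
#' Fuzzy values are serialized with 12 decimal digits; the level and
#' provenance travel in a leading comment line.
#'
#' @param x a \code{copam}.
#' @param path file path.
#' @export
write_copam <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s provenance=%s", x$level,
                     paste(x$provenance, collapse = ",")), con)
  writeLines(paste(c("cluster", colnames(x$membership)),
                   collapse = "\t"), con)
  for (k in seq_len(nrow(x$membership)))
    writeLines(paste(c(rownames(x$membership)[k],
                       formatC(x$membership[k, ], digits = 12,
                               format = "f")), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_copam
#' @export
read_copam <- function(path) {
  lines <- readLines(path)
  tags <- regmatches(lines[1L],
                     regexec("# level=(\\S+) provenance=(\\S*)",
                             lines[1L]))[[1L]]
  body <- utils::read.table(text = lines[-1L], sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
  m <- as.matrix(body)
  m <- sweep(m, 2L, colSums(m), "/")  # undo 12-digit rounding drift
  prov <- if (nzchar(tags[3L])) strsplit(tags[3L], ",")[[1L]]
          else character()
  copam(m, tags[2L], prov)
}
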
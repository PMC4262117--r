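#' Construct an expression dataset
#'
#' An \code{expression_dataset} holds one genes-by-conditions expression
#' matrix together with its identifiers and its position in the fixed
#' preprocessing chain (raw -> normalized -> summarized -> standardized).
#' All datasets entering a consensus run must share the same ordered gene
#' universe.
#'
#' @param values numeric matrix, rows = genes, columns = samples or
#'   conditions.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param condition_labels character vector of column labels.
#' @param dataset_id short label for the dataset (e.g. \code{"D01"}).
#' @param state preprocessing state, one of \code{"raw"}, \code{"normalized"},
#'   \code{"summarized"}, \code{"standardized"}.
#' @param flagged_genes character vector of genes zeroed out during
#'   standardization because their expression was constant.
#'
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(values, gene_ids, condition_labels,
                               dataset_id = "D", state = "raw",
                               flagged_genes = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(condition_labels) != ncol(values))
    stop("condition_labels length does not match column count")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene IDs: ", paste(dup, collapse = ", "))
  if (anyNA(values))
    stop("missing values in expression matrix for dataset ", dataset_id)
  state <- match.arg(state, c("raw", "normalized", "summarized",
                              "standardized"))
  rownames(values) <- gene_ids
  colnames(values) <- condition_labels
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 condition_labels = as.character(condition_labels),
                 dataset_id = dataset_id,
                 state = state,
                 flagged_genes = as.character(flagged_genes)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset ", x$dataset_id, ": ",
      nrow(x$values), " genes x ", ncol(x$values), " conditions [",
      x$state, "]\n", sep = "")
  if (length(x$flagged_genes))
    cat("  flagged constant genes: ", length(x$flagged_genes), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

.check_state <- function(dataset, expected, op) {
  if (!dataset$state %in% expected)
    stop(op, " requires a dataset in state ",
         paste(sQuote(expected), collapse = " or "),
         " but ", dataset$dataset_id, " is in state ",
         sQuote(dataset$state),
         " (chain: raw -> normalized -> summarized -> standardized)")
  invisible(TRUE)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample labels followed by one row per gene:
#' gene identifier, then numeric values.  The gene order of the file is
#' preserved.
#'
#' @param path path to a tab-delimited text file.
#' @param dataset_id label for the dataset; defaults to the file name
#'   without extension.
#' @return An \code{\link{expression_dataset}} in state \code{"raw"}.
#' @export
read_expression_matrix <- function(path,
                                   dataset_id = sub("\\.[^.]*$", "",
                                                    basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("file ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the gene-ID column
  n_body <- length(fields[[2L]])
  if (length(header) == n_body) {
    condition_labels <- header[-1L]
  } else if (length(header) == n_body - 1L) {
    condition_labels <- header
  } else {
    stop("header of ", path, " has ", length(header),
         " fields but line 2 has ", n_body)
  }
  n_col <- length(condition_labels)
  gene_ids <- character(length(fields) - 1L)
  values <- matrix(NA_real_, length(fields) - 1L, n_col)
  for (i in seq_along(fields)[-1L]) {
    row <- fields[[i]]
    if (length(row) != n_col + 1L)
      stop("line ", i, " of ", path, " has ", length(row),
           " fields, expected ", n_col + 1L)
    gene_ids[i - 1L] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric value ", sQuote(row[-1L][bad]), " at line ", i,
           ", column ", bad + 1L, " of ", path)
    }
    values[i - 1L, ] <- v
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene IDs in ", path, ": ", paste(dup, collapse = ", "))
  expression_dataset(values, gene_ids, condition_labels,
                     dataset_id = dataset_id, state = "raw")
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of \code{\link{read_expression_matrix}} up to numeric formatting.
#'
#' @param dataset an \code{expression_dataset}.
#' @param path output file path.
#' @export
write_expression_matrix <- function(dataset, path) {
  df <- data.frame(gene = dataset$gene_ids, dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a one-identifier-per-line gene universe file
#' @param path file path.
#' @return character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Read a two-column sample-to-condition replicate map
#'
#' @param path tab-delimited file with columns sample_label, condition_label
#'   (no header).
#' @return data frame with columns \code{sample} and \code{condition}.
#' @export
read_replicate_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "condition"),
                          colClasses = "character")
  df
}

#' Align datasets to a common gene universe
#'
#' Reorders every dataset's rows to the universe order and drops genes
#' outside the universe.  In \code{"strict"} mode a universe gene missing
#' from any dataset is an error; in \code{"intersection"} mode the universe
#' is shrunk to the genes present in every dataset (preserving universe
#' order), mirroring the practice of discarding genes not measured on all
#' platforms.
#'
#' @param datasets list of \code{expression_dataset} objects.
#' @param universe ordered character vector of gene IDs.
#' @param mode \code{"strict"} or \code{"intersection"}.
#' @return list with elements \code{datasets} (aligned list) and
#'   \code{universe} (the universe actually used).
#' @export
align_gene_universe <- function(datasets, universe,
                                mode = c("strict", "intersection")) {
  mode <- match.arg(mode)
  universe <- as.character(universe)
  if (mode == "intersection") {
    for (d in datasets) universe <- universe[universe %in% d$gene_ids]
  } else {
    for (d in datasets) {
      missing <- setdiff(universe, d$gene_ids)
      if (length(missing))
        stop("gene(s) ", paste(missing, collapse = ", "),
             " absent from dataset ", d$dataset_id,
             " (use mode = \"intersection\" to drop them)")
    }
  }
  if (!length(universe)) stop("empty gene universe after alignment")
  aligned <- lapply(datasets, function(d) {
    idx <- match(universe, d$gene_ids)
    expression_dataset(d$values[idx, , drop = FALSE], universe,
                       d$condition_labels, d$dataset_id, d$state,
                       intersect(d$flagged_genes, universe))
  })
  list(datasets = aligned, universe = universe)
}

#' Quantile-normalize the columns of a dataset
#'
#' Forces every column to share the same empirical distribution (the
#' column-wise mean of the rank-ordered values), preserving within-column
#' ranks; ties receive the mean of the quantiles they span.
#'
#' @param dataset an \code{expression_dataset} in state \code{"raw"}.
#' @return The dataset in state \code{"normalized"}.
#' @export
quantile_normalize <- function(dataset) {
  .check_state(dataset, "raw", "quantile_normalize")
  v <- dataset$values
  if (ncol(v) < 2L) {
    warning("single-column dataset ", dataset$dataset_id,
            ": quantile normalization is a no-op")
  } else {
    v <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(v) <- dimnames(dataset$values)
  }
  expression_dataset(v, dataset$gene_ids, dataset$condition_labels,
                     dataset$dataset_id, "normalized")
}

#' Summarize replicate columns by their median
#'
#' Collapses replicate sample columns to one column per condition using
#' the per-gene median.  Condition order follows first appearance in the
#' map.
#'
#' @param dataset an \code{expression_dataset} in state \code{"normalized"}.
#' @param map data frame with columns \code{sample}, \code{condition}
#'   covering every column of the dataset; \code{NULL} treats each column
#'   as its own condition.
#' @return The dataset in state \code{"summarized"}.
#' @export
summarize_replicates <- function(dataset, map = NULL) {
  .check_state(dataset, "normalized", "summarize_replicates")
  if (is.null(map))
    map <- data.frame(sample = dataset$condition_labels,
                      condition = dataset$condition_labels)
  if (!all(dataset$condition_labels %in% map$sample))
    stop("replicate map does not cover columns: ",
         paste(setdiff(dataset$condition_labels, map$sample),
               collapse = ", "))
  cond_of <- map$condition[match(dataset$condition_labels, map$sample)]
  conditions <- unique(cond_of)  # first-appearance order
  out <- vapply(conditions, function(cc) {
    cols <- which(cond_of == cc)
    if (length(cols) == 1L) dataset$values[, cols]
    else apply(dataset$values[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(dataset$values)))
  out <- matrix(out, nrow = nrow(dataset$values),
                dimnames = list(dataset$gene_ids, conditions))
  expression_dataset(out, dataset$gene_ids, conditions,
                     dataset$dataset_id, "summarized")
}

#' Standardize gene profiles to zero mean and unit standard deviation
#'
#' Each row is mean-centred and scaled by its population standard deviation
#' (divide by the number of conditions).  Constant rows cannot be scaled;
#' they are set to all zeros and recorded in \code{flagged_genes} so the
#' gene universe stays aligned across datasets.  Idempotent.
#'
#' @param dataset an \code{expression_dataset} in state \code{"summarized"}
#'   (or \code{"standardized"}, in which case re-standardizing is a no-op
#'   up to numerical tolerance).
#' @param sd_type \code{"population"} (divide by N, the default) or
#'   \code{"sample"} (divide by N - 1).
#' @return The dataset in state \code{"standardized"}.
#' @export
standardize_genes <- function(dataset,
                              sd_type = c("population", "sample")) {
  .check_state(dataset, c("summarized", "standardized"),
               "standardize_genes")
  sd_type <- match.arg(sd_type)
  v <- dataset$values
  n <- ncol(v)
  ctr <- v - rowMeans(v)
  denom <- if (sd_type == "population") n else n - 1L
  s <- sqrt(rowSums(ctr^2) / denom)
  flat <- s < 1e-12
  s[flat] <- 1
  out <- ctr / s
  out[flat, ] <- 0
  expression_dataset(out, dataset$gene_ids, dataset$condition_labels,
                     dataset$dataset_id, "standardized",
                     flagged_genes = union(dataset$flagged_genes,
                                           dataset$gene_ids[flat]))
}

#' Run the full preprocessing chain on one dataset
#'
#' Applies, in the fixed order, quantile normalization, median replicate
#' summarization, and per-gene z-scoring.
#'
#' @inheritParams summarize_replicates
#' @inheritParams standardize_genes
#' @return The dataset in state \code{"standardized"}, with an attribute
#'   \code{"log"} recording the matrix shape after every stage.
#' @export
preprocess_dataset <- function(dataset, map = NULL,
                               sd_type = c("population", "sample")) {
  log <- sprintf("%s raw %dx%d", dataset$dataset_id,
                 nrow(dataset$values), ncol(dataset$values))
  dataset <- quantile_normalize(dataset)
  log <- c(log, sprintf("%s normalized %dx%d", dataset$dataset_id,
                        nrow(dataset$values), ncol(dataset$values)))
  dataset <- summarize_replicates(dataset, map)
  log <- c(log, sprintf("%s summarized %dx%d", dataset$dataset_id,
                        nrow(dataset$values), ncol(dataset$values)))
  dataset <- standardize_genes(dataset, sd_type)
  log <- c(log, sprintf("%s standardized %dx%d", dataset$dataset_id,
                        nrow(dataset$values), ncol(dataset$values)))
  attr(dataset, "log") <- log
  dataset
}
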
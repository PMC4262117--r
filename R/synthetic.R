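#' Configuration for the synthetic multi-dataset generator
#'
#' Describes a collection of expression datasets sharing a gene universe,
#' mimicking the structure of a multi-study microarray compendium: every
#' dataset has its own number of conditions, two planted gene modules whose
#' latent templates are strongly anti-correlated with zero lag in every
#' dataset, optional confounder modules coherent in only a random half of
#' the datasets, optional within-condition replicates, and a bulk of
#' background genes with no cross-dataset consistency.
#'
#' @param n_genes size of the gene universe.
#' @param n_datasets number of datasets.
#' @param conditions_range integer range (inclusive) from which each
#'   dataset's number of conditions is drawn.
#' @param module_sizes lengths of the two planted anti-phase modules.
#' @param module_anticorrelation target Pearson correlation between the
#'   two modules' latent templates (enforced exactly within each dataset
#'   by orthogonalized mixing).
#' @param gene_noise_sd standard deviation of the i.i.d. gene-level noise
#'   added around the unit-variance templates.
#' @param n_confounder_modules number of half-consistent confounder
#'   modules.
#' @param confounder_size genes per confounder module.
#' @param replicates_per_condition replicate columns per condition.
#' @param replicate_noise_sd extra measurement noise per replicate column.
#' @param seed RNG seed; the whole collection is a deterministic function
#'   of the configuration.
#' @return A validated list of class \code{generator_config}.
#' @export
generator_config <- function(n_genes = 1000L,
                             n_datasets = 10L,
                             conditions_range = c(4L, 49L),
                             module_sizes = c(160L, 50L),
                             module_anticorrelation = -0.95,
                             gene_noise_sd = 0.4,
                             n_confounder_modules = 2L,
                             confounder_size = 30L,
                             replicates_per_condition = 1L,
                             replicate_noise_sd = 0.2,
                             seed = 0L) {
  stopifnot(n_genes >= 1, n_datasets >= 1, length(module_sizes) == 2,
            conditions_range[1L] >= 2,
            conditions_range[2L] >= conditions_range[1L],
            module_anticorrelation < 0, module_anticorrelation >= -1,
            gene_noise_sd > 0, replicate_noise_sd > 0,
            replicates_per_condition >= 1)
  planted <- sum(module_sizes) + n_confounder_modules * confounder_size
  if (planted > n_genes)
    stop("module and confounder genes (", planted,
         ") exceed n_genes (", n_genes, ")")
  structure(list(n_genes = as.integer(n_genes),
                 n_datasets = as.integer(n_datasets),
                 conditions_range = as.integer(conditions_range),
                 module_sizes = as.integer(module_sizes),
                 module_anticorrelation = module_anticorrelation,
                 gene_noise_sd = gene_noise_sd,
                 n_confounder_modules = as.integer(n_confounder_modules),
                 confounder_size = as.integer(confounder_size),
                 replicates_per_condition =
                   as.integer(replicates_per_condition),
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# smooth band-limited template over n ordered conditions, population-z-scored
.fourier_template <- function(n, n_harmonics = 3L) {
  s <- seq_len(n) / n
  t <- numeric(n)
  for (h in seq_len(n_harmonics))
    t <- t + stats::rnorm(1, sd = 1 / h) *
      sin(2 * pi * h * s + stats::runif(1, 0, 2 * pi))
  .zscore_pop(t)
}

.zscore_pop <- function(v) {
  v <- v - mean(v)
  s <- sqrt(mean(v^2))
  if (s < 1e-12) return(rep(0, length(v)))
  v / s
}

#' Generate a synthetic multi-dataset expression collection
#'
#' Per dataset, a smooth latent template \code{t} (random Fourier sum over
#' the ordered conditions) drives module A; module B follows a template
#' with exactly the configured negative correlation to \code{t}, built by
#' mixing \code{-t} with an orthogonalized second smooth component, so the
#' two modules are anti-phase with zero lag by construction.  Confounder
#' modules follow fresh templates in a seeded random half of the datasets
#' and behave as background elsewhere; background genes are i.i.d. noise
#' redrawn per dataset.  Values are exponentiated onto a positive raw
#' scale so the full preprocessing chain (quantile normalization, replicate
#' summarization, z-scoring) has real work to do.
#'
#' @param config a \code{\link{generator_config}}.
#' @return List with \code{datasets} (raw \code{expression_dataset}s),
#'   \code{replicate_maps} (per dataset, \code{NULL} when no replicates),
#'   and \code{truth} — a list holding \code{assignment} (factor per gene:
#'   \code{moduleA}, \code{moduleB}, \code{confounder<i>},
#'   \code{background}), \code{templates} (per dataset, the module A and B
#'   templates), \code{template_correlation} (realized per-dataset r), and
#'   \code{confounder_datasets}.
#' @export
generate_collection <- function(config = generator_config()) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))
  sizes <- config$module_sizes
  nc <- config$n_confounder_modules
  assignment <- rep("background", G)
  idxA <- seq_len(sizes[1L])
  idxB <- seq_len(sizes[2L]) + sizes[1L]
  assignment[idxA] <- "moduleA"
  assignment[idxB] <- "moduleB"
  conf_idx <- list()
  offset <- sum(sizes)
  for (ci in seq_len(nc)) {
    conf_idx[[ci]] <- offset + seq_len(config$confounder_size)
    assignment[conf_idx[[ci]]] <- paste0("confounder", ci)
    offset <- offset + config$confounder_size
  }
  # each confounder is coherent in a random half of the datasets
  conf_sets <- lapply(seq_len(nc), function(ci)
    sort(sample.int(config$n_datasets,
                    max(1L, floor(config$n_datasets / 2)))))
  Ns <- sample(seq(config$conditions_range[1L],
                   config$conditions_range[2L]),
               config$n_datasets, replace = TRUE)
  alpha <- -config$module_anticorrelation
  datasets <- vector("list", config$n_datasets)
  maps <- vector("list", config$n_datasets)
  templates <- vector("list", config$n_datasets)
  r_real <- numeric(config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    N <- Ns[d]
    t_a <- .fourier_template(N)
    e <- .fourier_template(N)
    # component of e orthogonal to t_a (population inner product)
    e_perp <- .zscore_pop(e - mean(e * t_a) * t_a)
    if (all(e_perp == 0)) e_perp <- .zscore_pop(stats::rnorm(N))
    t_b <- -(alpha * t_a + sqrt(1 - alpha^2) * e_perp)
    templates[[d]] <- list(A = t_a, B = t_b)
    r_real[d] <- stats::cor(t_a, t_b)
    signal <- matrix(stats::rnorm(G * N), G, N)  # background
    sdn <- config$gene_noise_sd
    signal[idxA, ] <- rep(t_a, each = length(idxA)) +
      stats::rnorm(length(idxA) * N, sd = sdn)
    signal[idxB, ] <- rep(t_b, each = length(idxB)) +
      stats::rnorm(length(idxB) * N, sd = sdn)
    for (ci in seq_len(nc)) {
      if (d %in% conf_sets[[ci]]) {
        t_c <- .fourier_template(N)
        signal[conf_idx[[ci]], ] <-
          rep(t_c, each = length(conf_idx[[ci]])) +
          stats::rnorm(length(conf_idx[[ci]]) * N, sd = sdn)
      }
    }
    r <- config$replicates_per_condition
    cond_labels <- sprintf("c%02d", seq_len(N))
    if (r > 1L) {
      cols <- rep(seq_len(N), each = r)
      raw <- signal[, cols] +
        stats::rnorm(G * N * r, sd = config$replicate_noise_sd)
      sample_labels <- sprintf("%s_r%d", cond_labels[cols],
                               rep(seq_len(r), N))
      maps[[d]] <- data.frame(sample = sample_labels,
                              condition = cond_labels[cols])
    } else {
      raw <- signal
      sample_labels <- cond_labels
      # maps[[d]] stays NULL: no replicates to summarize
    }
    datasets[[d]] <- expression_dataset(exp(raw), gene_ids,
                                        sample_labels,
                                        dataset_id = sprintf("D%02d", d),
                                        state = "raw")
  }
  list(datasets = datasets,
       replicate_maps = maps,
       truth = list(assignment = factor(assignment),
                    gene_ids = gene_ids,
                    templates = templates,
                    template_correlation = r_real,
                    confounder_datasets = conf_sets))
}

#' Score recovery of planted modules by a binarized partition
#'
#' For each planted module, the best Jaccard index between the module's
#' gene set and any cluster's gene set.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generate_collection}} output.
#' @param partition a \code{binarized_partition} over the same gene
#'   universe.
#' @param modules which ground-truth labels to score.
#' @return Named numeric vector of Jaccard indices, plus attribute
#'   \code{"best_cluster"} naming the best-matching cluster per module.
#' @export
score_recovery <- function(truth, partition,
                           modules = c("moduleA", "moduleB")) {
  genes <- colnames(partition$membership)
  out <- numeric(length(modules))
  best <- character(length(modules))
  names(out) <- modules
  for (i in seq_along(modules)) {
    mod_genes <- truth$gene_ids[truth$assignment == modules[i]]
    jac <- vapply(seq_len(nrow(partition$membership)), function(k) {
      cl_genes <- genes[partition$membership[k, ] == 1]
      u <- length(union(mod_genes, cl_genes))
      if (u == 0) 0 else length(intersect(mod_genes, cl_genes)) / u
    }, numeric(1))
    out[i] <- max(jac)
    best[i] <- rownames(partition$membership)[which.max(jac)]
  }
  attr(out, "best_cluster") <- best
  out
}

#' Write a synthetic collection to disk
#'
#' Emits one TSV expression matrix per dataset, replicate maps where
#' replicates exist, the gene-universe list, and a ground-truth table.
#'
#' @param collection output of \code{\link{generate_collection}}.
#' @param dir output directory (created if needed).
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(collection$datasets)) {
    d <- collection$datasets[[i]]
    write_expression_matrix(d, file.path(dir, paste0(d$dataset_id,
                                                     ".tsv")))
    m <- collection$replicate_maps[[i]]
    if (!is.null(m))
      utils::write.table(m, file.path(dir, paste0(d$dataset_id,
                                                  "_replicates.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  writeLines(collection$truth$gene_ids, file.path(dir, "genes.txt"))
  utils::write.table(
    data.frame(gene = collection$truth$gene_ids,
               module = as.character(collection$truth$assignment)),
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
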
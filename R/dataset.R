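#' Expression dataset
#'
#' Container for a samples-by-genes expression matrix with a binary outcome
#' label per sample (1 = poor outcome, i.e. an event within five years;
#' 0 = good outcome) and an optional binary estrogen-receptor (ER) status.
#'
#' @param values Numeric matrix, rows = samples, columns = genes, with
#'   row and column names (sample ids / gene ids) or explicit id arguments.
#' @param labels Integer/numeric vector of 0/1 outcome labels, one per sample.
#' @param sample_ids,gene_ids Optional character vectors overriding dimnames.
#' @param er_status Optional 0/1 vector of ER status per sample.
#' @param name Dataset name (used when merging and reporting).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, labels, sample_ids = rownames(values),
                               gene_ids = colnames(values), er_status = NULL,
                               name = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(gene_ids)) stopf("gene ids are required")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stopf("%d sample ids for %d rows", length(sample_ids), nrow(values))
  if (length(gene_ids) != ncol(values))
    stopf("%d gene ids for %d columns", length(gene_ids), ncol(values))
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  labels <- as.integer(labels)
  if (length(labels) != nrow(values)) stopf("one label per sample required")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0 (good) or 1 (poor)")
  if (!is.null(er_status)) {
    er_status <- as.integer(er_status)
    if (length(er_status) != nrow(values) || !all(er_status %in% c(0L, 1L)))
      stopf("er_status must be one 0/1 value per sample")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, labels = labels, er_status = er_status,
                 name = name),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d samples x %d genes (%d poor / %d good)\n",
              x$name, nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

n_samples <- function(ds) nrow(ds$values)
gene_ids <- function(ds) colnames(ds$values)
sample_ids <- function(ds) rownames(ds$values)

# Row subset preserving all per-sample metadata.
subset_samples <- function(ds, idx, name = ds$name) {
  expression_dataset(ds$values[idx, , drop = FALSE], ds$labels[idx],
                     er_status = if (!is.null(ds$er_status)) ds$er_status[idx],
                     name = name)
}

#' Per-gene z-normalization
#'
#' Standardizes every gene column to mean 0 and standard deviation 1
#' (sample sd, n-1 denominator) within the dataset.
#'
#' @param ds An `ExpressionDataset`.
#' @return The normalized `ExpressionDataset`; sample and gene order preserved.
#' @export
znormalize <- function(ds) {
  v <- ds$values
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  bad <- which(sd <= 0 | !is.finite(sd))
  if (length(bad))
    stopf("constant gene column(s): %s",
          paste(colnames(v)[bad], collapse = ", "))
  v <- sweep(sweep(v, 2L, mu, "-"), 2L, sd, "/")
  out <- ds
  out$values <- v
  out
}

#' Restrict a dataset to a gene universe
#'
#' Keeps exactly the genes present in both the dataset and `universe`,
#' preserving the dataset's original column order.
#'
#' @param ds An `ExpressionDataset`.
#' @param universe Character vector of gene ids.
#' @return The restricted `ExpressionDataset`.
#' @export
restrict_genes <- function(ds, universe) {
  keep <- gene_ids(ds) %in% universe
  if (!any(keep)) stopf("no genes of '%s' are in the given universe", ds$name)
  out <- ds
  out$values <- ds$values[, keep, drop = FALSE]
  out
}

#' Merge datasets into one pooled, renormalized dataset
#'
#' Row-concatenates cohorts sharing an identical gene universe, prefixing
#' sample ids with the cohort name, then z-normalizes the pooled matrix.
#'
#' @param datasets List of `ExpressionDataset`s with identical `gene_ids`.
#' @param name Name for the merged dataset.
#' @return The merged, z-normalized `ExpressionDataset`.
#' @export
merge_datasets <- function(datasets, name = "merged") {
  stopifnot(length(datasets) >= 1L)
  ref <- gene_ids(datasets[[1L]])
  for (ds in datasets[-1L]) {
    if (!identical(gene_ids(ds), ref)) {
      diff <- c(setdiff(gene_ids(ds), ref), setdiff(ref, gene_ids(ds)))
      stopf("gene universes differ between '%s' and '%s': %s",
            datasets[[1L]]$name, ds$name,
            paste(utils::head(diff, 10L), collapse = ", "))
    }
  }
  values <- do.call(rbind, lapply(datasets, function(d) {
    v <- d$values
    rownames(v) <- paste(d$name, rownames(v), sep = ":")
    v
  }))
  labels <- unlist(lapply(datasets, `[[`, "labels"), use.names = FALSE)
  ers <- lapply(datasets, `[[`, "er_status")
  er <- if (all(!vapply(ers, is.null, logical(1L))))
    unlist(ers, use.names = FALSE) else NULL
  znormalize(expression_dataset(values, labels, er_status = er, name = name))
}
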
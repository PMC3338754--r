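# File IO: expression TSV, label TSV, GMT gene sets, two-column edge lists.
# All formats are plain text; round-trips reproduce the in-memory objects
# (floats written with 10 significant digits).

#' Write / read an expression dataset
#'
#' The expression matrix is a tab-separated table with samples in rows,
#' gene ids in the header and the sample id in the first column
#' (`sample_id`).  Labels (and optional ER status) live in a separate
#' two/three-column TSV with a header.
#'
#' @param ds An `ExpressionDataset`.
#' @param expr_path Path of the expression TSV.
#' @param labels_path Path of the labels TSV.
#' @param name Dataset name to attach on read.
#' @return `read_expression_dataset` returns an `ExpressionDataset`;
#'   `write_expression_dataset` returns the paths invisibly.
#' @export
write_expression_dataset <- function(ds, expr_path, labels_path) {
  tab <- cbind(sample_id = sample_ids(ds),
               as.data.frame(signif(ds$values, 10L)))
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample_id = sample_ids(ds), label = ds$labels)
  if (!is.null(ds$er_status)) lab$er_status <- ds$er_status
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, labels_path))
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(expr_path, labels_path, name = "dataset") {
  header <- strsplit(readLines(expr_path, n = 1L), "\t", fixed = TRUE)[[1L]]
  genes <- header[-1L]
  if (anyDuplicated(genes))
    stopf("%s: duplicate gene id(s) in header: %s", expr_path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  tab <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  values <- matrix(NA_real_, nrow(tab), length(genes),
                   dimnames = list(tab[[1L]], genes))
  for (j in seq_along(genes)) {
    col <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    if (anyNA(col))
      stopf("%s: malformed value at line %d", expr_path,
            which(is.na(col))[1L] + 1L)
    values[, j] <- col
  }
  lab <- utils::read.table(labels_path, sep = "\t", header = TRUE)
  if (!all(c("sample_id", "label") %in% names(lab)))
    stopf("%s: expected columns sample_id, label", labels_path)
  m <- match(rownames(values), lab$sample_id)
  if (anyNA(m)) stopf("%s: missing label for sample(s)", labels_path)
  expression_dataset(values, lab$label[m],
                     er_status = if ("er_status" %in% names(lab))
                       lab$er_status[m],
                     name = name)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param coll A `GeneSetCollection`.
#' @param name Collection name to attach on read.
#' @return `read_gmt` returns a `GeneSetCollection`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("%s: malformed GMT line %d (need name, description, >=1 gene)",
            path, i)
    sets[[f[[1L]]]] <- unique(f[-(1:2)])
  }
  if (length(sets) != length(lines)) stopf("%s: duplicate set name", path)
  gene_set_collection(sets, name = name)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(coll, path) {
  writeLines(vapply(names(coll$sets), function(nm) {
    paste(c(nm, "na", coll$sets[[nm]]), collapse = "\t")
  }, character(1L)), path)
  invisible(path)
}

#' Read / write two-column edge lists
#'
#' One undirected edge per line as two tab-separated gene ids; lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @param net A `GeneNetwork`.
#' @param name Network name to attach on read.
#' @return `read_edge_list` returns a `GeneNetwork`.
#' @export
read_edge_list <- function(path, name = basename(path)) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 2L))
    stopf("%s: malformed edge at line %d", path, idx[which(n_fields != 2L)[1L]])
  edges <- do.call(rbind, parts)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops))
    stopf("%s: self-loop at line %d", path, idx[which(loops)[1L]])
  gene_network(edges, name = name)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(net, path) {
  lines <- apply(net$edges, 1L, paste, collapse = "\t")
  isolated <- setdiff(net$nodes, as.vector(net$edges))
  if (length(isolated))
    lines <- c(lines, paste("# isolated:", paste(isolated, collapse = " ")))
  writeLines(as.character(lines), path)
  invisible(path)
}
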
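#' Undirected gene network
#'
#' A secondary data source: an undirected network over its own gene universe.
#' Self-loops are rejected and each undirected edge is stored once
#' (endpoints in lexicographic order).
#'
#' @param edges Two-column character matrix or data frame of gene-id pairs.
#' @param nodes Optional character vector of node ids; defaults to the set of
#'   edge endpoints.  Extra isolated nodes are allowed.
#' @param name Source name.
#' @return An object of class `GeneNetwork`.
#' @export
gene_network <- function(edges, nodes = NULL, name = "network") {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    if (ncol(edges) != 2L) stopf("edges must have two columns")
    mode(edges) <- "character"
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L]
    stopf("self-loop(s) on: %s", paste(unique(bad), collapse = ", "))
  }
  # canonical order inside each pair, then dedupe
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  if (!all(edges %in% nodes)) stopf("edge endpoint missing from node set")
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(as.data.frame(net$edges,
                                              stringsAsFactors = FALSE),
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Node degrees of a network
#' @param net A `GeneNetwork`.
#' @return Named integer vector of degrees (isolated nodes have degree 0).
#' @export
network_degrees <- function(net) {
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(as.vector(net$edges))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# Neighbor list as a named list of sorted character vectors.
adjacency_list <- function(net) {
  adj <- lapply(stats::setNames(vector("list", length(net$nodes)), net$nodes),
                function(x) character())
  if (nrow(net$edges)) {
    sp <- split(c(net$edges[, 2L], net$edges[, 1L]),
                c(net$edges[, 1L], net$edges[, 2L]))
    for (nm in names(sp)) adj[[nm]] <- sort(unique(sp[[nm]]))
  }
  adj
}

#' Restrict a network to a gene universe
#'
#' Drops nodes (and incident edges) outside `universe`; used to remove
#' network proteins for which no expression data is available before any
#' subnetwork search.
#'
#' @param net A `GeneNetwork`.
#' @param universe Character vector of gene ids to keep.
#' @return The induced subnetwork as a `GeneNetwork`.
#' @export
restrict_network <- function(net, universe) {
  keep_nodes <- intersect(net$nodes, universe)
  keep <- net$edges[, 1L] %in% keep_nodes & net$edges[, 2L] %in% keep_nodes
  gene_network(net$edges[keep, , drop = FALSE], nodes = keep_nodes,
               name = net$name)
}

#' Gene-set collection
#'
#' A named collection of gene sets (pathways), each a character vector of
#' gene ids, over its own gene universe.
#'
#' @param sets Named list of character vectors; names must be unique and
#'   every set non-empty.
#' @param name Source name.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, name = "genesets") {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stopf("set names must be present and unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stopf("empty gene set(s) not allowed")
  structure(list(sets = sets, name = name), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets (sizes %s)\n", x$name,
              length(x$sets),
              if (length(x$sets)) paste0(min(lengths(x$sets)), "-",
                                         max(lengths(x$sets))) else "-"))
  invisible(x)
}

#' Restrict a gene-set collection to a gene universe
#'
#' Intersects every set with `universe` and drops sets left empty.
#'
#' @param coll A `GeneSetCollection`.
#' @param universe Character vector of gene ids to keep.
#' @return The restricted `GeneSetCollection`.
#' @export
restrict_gene_sets <- function(coll, universe) {
  sets <- lapply(coll$sets, intersect, universe)
  structure(list(sets = sets[lengths(sets) > 0L], name = coll$name),
            class = "GeneSetCollection")
}

# Union of all gene ids mentioned by a secondary source.
source_universe <- function(src) {
  if (inherits(src, "GeneNetwork")) src$nodes
  else if (inherits(src, "GeneSetCollection")) sort(unique(unlist(src$sets,
                                                                  use.names = FALSE)))
  else stopf("not a secondary source")
}
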
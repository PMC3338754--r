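# Cross-dataset signature stability: Fisher-exact overlap of the gene sets
# selected independently from different cohorts, with a size-matched
# single-gene control and a sampling-corrected Jaccard index.

#' Signature of a dataset under one extraction method
#'
#' The union of the member genes of the `top_n` ranked features extracted
#' from the full dataset.  The selection universe is all measured genes for
#' single genes and the measured part of the secondary source for composite
#' features.
#'
#' @param dataset An `ExpressionDataset`.
#' @param method Extractor name, see [extract_features()].
#' @param secondary Secondary source (ignored for `"sg"`).
#' @param top_n Number of top features whose genes are pooled.
#' @param params Extractor parameters.
#' @return A `SignatureSet`: list with `dataset_name`, `method`, `gene_ids`,
#'   `universe`.
#' @export
signature_genes <- function(dataset, method, secondary = NULL, top_n = 50L,
                            params = NULL) {
  feats <- extract_features(dataset, method, secondary, params)
  top <- feats$features[seq_len(min(top_n, length(feats$features)))]
  genes <- sort(unique(unlist(lapply(top, `[[`, "member_genes"),
                              use.names = FALSE)))
  universe <- if (method == "sg" || is.null(secondary)) gene_ids(dataset)
              else intersect(source_universe(secondary), gene_ids(dataset))
  signature_set(dataset$name, method, genes, universe)
}

#' @rdname signature_genes
#' @param dataset_name,gene_ids,universe Fields of the signature.
#' @export
signature_set <- function(dataset_name, method, gene_ids, universe) {
  gene_ids <- unique(as.character(gene_ids))
  universe <- unique(as.character(universe))
  if (!all(gene_ids %in% universe))
    stopf("signature genes must lie inside the selection universe")
  structure(list(dataset_name = dataset_name, method = method,
                 gene_ids = gene_ids, universe = universe),
            class = "SignatureSet")
}

#' Fisher-exact overlap of two signatures
#'
#' One-sided enrichment p-value: the hypergeometric upper-tail probability
#' of observing at least the actual overlap between two signatures drawn
#' from the same universe.  Used as a *measure* of overlap (smaller p =
#' stronger overlap), not as a hypothesis test.
#'
#' @param a,b `SignatureSet`s sharing the same universe.
#' @return The p-value.
#' @export
fisher_overlap <- function(a, b) {
  if (!setequal(a$universe, b$universe))
    stopf("signatures come from different universes")
  u <- length(unique(a$universe))
  ov <- length(intersect(a$gene_ids, b$gene_ids))
  stats::phyper(ov - 1L, length(a$gene_ids), u - length(a$gene_ids),
                length(b$gene_ids), lower.tail = FALSE)
}

#' Size-matched single-gene control signature
#'
#' The `m` best genes by |t| on the full dataset, matching a composite
#' signature's gene count so single-gene and composite overlaps are
#' comparable.
#'
#' @param dataset An `ExpressionDataset`.
#' @param m Signature size (1 <= m <= number of genes).
#' @return A `SignatureSet` over all measured genes.
#' @export
size_matched_sg <- function(dataset, m) {
  if (m > ncol(dataset$values)) stopf("m exceeds the number of genes")
  feats <- rank_single_genes(dataset)
  genes <- vapply(feats$features[seq_len(m)], `[[`, character(1L),
                  "member_genes")
  signature_set(dataset$name, "sg_control", genes, gene_ids(dataset))
}

#' Jaccard overlap with a sampling null
#'
#' Jaccard index of two signatures plus an empirical p-value correcting for
#' the size of the selection universe: `n_draws` random signature pairs of
#' matched sizes are drawn from the universe and
#' `p = (1 + #(J_null >= J)) / (1 + n_draws)`.
#'
#' @param a,b `SignatureSet`s sharing the same universe.
#' @param n_draws Number of null draws.
#' @param seed Integer seed.
#' @return List with `jaccard` and `empirical_p`.
#' @export
jaccard_with_null <- function(a, b, n_draws = 1000L, seed = 1L) {
  if (!setequal(a$universe, b$universe))
    stopf("signatures come from different universes")
  u <- unique(a$universe)
  jac <- function(x, y) {
    length(intersect(x, y)) / length(union(x, y))
  }
  j <- jac(a$gene_ids, b$gene_ids)
  null <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    jac(sample(u, length(a$gene_ids)), sample(u, length(b$gene_ids))),
    numeric(1L)))
  list(jaccard = j, empirical_p = (1 + sum(null >= j)) / (1 + n_draws))
}

#' Cross-dataset stability report
#'
#' For every unordered pair of cohorts and each requested method: the
#' Fisher-exact overlap of the two signatures, the sampling-corrected
#' Jaccard index, and the same quantities for size-matched single-gene
#' control signatures (matched to the mean composite signature size of the
#' pair).  D cohorts yield `choose(D, 2)` rows per method.
#'
#' @param datasets List of `ExpressionDataset`s sharing a gene universe.
#' @param methods Character vector of extractor names.
#' @param secondary Secondary source used by composite methods.
#' @param top_n Number of top features per signature.
#' @param params Extractor parameters.
#' @param n_draws,seed Passed to [jaccard_with_null()].
#' @return Data frame with one row per (method, dataset pair).
#' @export
stability_report <- function(datasets, methods = "sg", secondary = NULL,
                             top_n = 50L, params = NULL, n_draws = 200L,
                             seed = 1L) {
  rows <- list()
  for (method in methods) {
    sigs <- lapply(datasets, signature_genes, method = method,
                   secondary = if (method == "sg") NULL else secondary,
                   top_n = top_n, params = params)
    for (i in seq_along(datasets)) for (j in seq_along(datasets)) {
      if (i >= j) next
      a <- sigs[[i]]; b <- sigs[[j]]
      fp <- fisher_overlap(a, b)
      jn <- jaccard_with_null(a, b, n_draws, seed)
      m_ctrl <- max(1L, round(mean(c(length(a$gene_ids),
                                     length(b$gene_ids)))))
      ca <- size_matched_sg(datasets[[i]], m_ctrl)
      cb <- size_matched_sg(datasets[[j]], m_ctrl)
      cfp <- fisher_overlap(ca, cb)
      cjn <- jaccard_with_null(ca, cb, n_draws, seed)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, dataset_a = a$dataset_name,
                   dataset_b = b$dataset_name,
                   signature_size_a = length(a$gene_ids),
                   signature_size_b = length(b$gene_ids),
                   fisher_p = fp, jaccard = jn$jaccard,
                   jaccard_p = jn$empirical_p,
                   control_fisher_p = cfp, control_jaccard = cjn$jaccard,
                   control_jaccard_p = cjn$empirical_p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
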
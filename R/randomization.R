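# Topology-preserving randomization of secondary data: the structure of
# networks and gene-set collections is kept intact while gene identities are
# permuted, destroying the biological information.

#' Permute the gene identities of a secondary source
#'
#' Applies one uniform random bijection over the source's own gene universe
#' (including genes not measured on the array) to every occurrence of every
#' gene.  Network degree sequences and gene-set size profiles are exactly
#' preserved.
#'
#' @param src A `GeneNetwork` or `GeneSetCollection`.
#' @param seed Integer seed for the permutation draw.
#' @param universe Optional permutation domain; defaults to the source's own
#'   gene universe.  Pass the measured genes to shuffle only within the
#'   measured subset.
#' @param mapping Optional explicit bijection (named character vector,
#'   old id -> new id) overriding the seeded random draw.
#' @return A source of the same class with permuted identities, its name
#'   suffixed with the seed.
#' @export
permute_identities <- function(src, seed, universe = NULL, mapping = NULL) {
  if (is.null(universe)) universe <- source_universe(src)
  universe <- sort(unique(universe))
  if (is.null(mapping)) {
    mapping <- with_seed(seed,
                         stats::setNames(sample(universe), universe))
  } else if (!setequal(names(mapping), unname(mapping))) {
    stopf("mapping must be a bijection")
  }
  relabel <- function(g) {
    hit <- g %in% names(mapping)
    g[hit] <- unname(mapping[g[hit]])
    g
  }
  name <- paste0(src$name, "_perm", seed)
  if (inherits(src, "GeneNetwork")) {
    edges <- src$edges
    edges[] <- relabel(as.vector(edges))
    gene_network(edges, nodes = relabel(src$nodes), name = name)
  } else if (inherits(src, "GeneSetCollection")) {
    gene_set_collection(lapply(src$sets, relabel), name = name)
  } else stopf("not a secondary source")
}

#' Real-versus-randomized secondary data experiment
#'
#' Re-runs the full paired evaluation on the real secondary source and on
#' `n_instances` identity-permuted instances of it.  For each instance a
#' one-sided paired Wilcoxon test asks whether the real AUCs are larger than
#' the instance's AUCs over the matched (train, test) pairs; Bonferroni
#' correction multiplies by the number of instances.
#'
#' @param datasets List of `ExpressionDataset`s.
#' @param method Extractor name (`"chuang"`, `"lee"`, `"taylor"`).
#' @param src The real secondary source.
#' @param n_instances Number of randomized instances.
#' @param seed Base seed; instance i uses `seed + i`.
#' @param alpha Significance level applied to the adjusted p-values.
#' @param ... Passed to [paired_setting()] (classifier kind, policy, params).
#' @return List with `real` (records), `instances` (list of records), and
#'   `tests` (data frame: instance, mean_auc, p_value, p_adjusted,
#'   rejected).
#' @export
randomization_experiment <- function(datasets, method, src,
                                     n_instances = 25L, seed = 1L,
                                     alpha = 0.05, ...) {
  real <- paired_setting(datasets, method = method, secondary = src, ...)
  instances <- list()
  tests <- NULL
  for (i in seq_len(n_instances)) {
    rnd <- permute_identities(src, seed + i)
    rec <- paired_setting(datasets, method = method, secondary = rnd, ...)
    instances[[i]] <- rec
    cmp <- compare_methods(real, rec, alternative = "greater",
                           n_comparisons = n_instances)
    tests <- rbind(tests,
                   data.frame(instance = i,
                              mean_auc = mean(rec$auc, na.rm = TRUE),
                              p_value = cmp$p_value,
                              p_adjusted = cmp$p_adjusted,
                              rejected = cmp$p_adjusted < alpha))
  }
  list(real = real, instances = instances,
       tests = tests %||% data.frame(instance = integer(), mean_auc =
                                       numeric(), p_value = numeric(),
                                     p_adjusted = numeric(),
                                     rejected = logical()))
}
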
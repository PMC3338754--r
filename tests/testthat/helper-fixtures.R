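# Shared fixtures and independent oracles used across the suite.

# small deterministic dataset: 3 informative genes among `n_genes`,
# two classes separated by `effect`
make_toy_dataset <- function(n = 40L, n_genes = 10L, effect = 2,
                             seed = 42L, name = "toy",
                             informative = 1:3) {
  set.seed(seed)
  labels <- rep(c(1L, 0L), c(n %/% 3, n - n %/% 3))
  labels <- sample(labels)
  values <- matrix(rnorm(n * n_genes), n, n_genes,
                   dimnames = list(sprintf("s%02d", 1:n),
                                   sprintf("g%03d", 1:n_genes)))
  values[labels == 1L, informative] <- values[labels == 1L, informative] +
    effect
  expression_dataset(values, labels, name = name)
}

fm_from_matrix <- function(values, labels) {
  colnames(values) <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  structure(list(values = values, provenance = colnames(values),
                 labels = as.integer(labels)), class = "FeatureMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# mutual information by direct joint-histogram computation
mi_oracle <- function(act, labels, n_bins) {
  rng <- range(act)
  if (rng[1] == rng[2]) bin <- rep(1L, length(act))
  else {
    width <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((act - rng[1]) / width) + 1L, n_bins)
  }
  mi <- 0
  for (b in unique(bin)) for (c in unique(labels)) {
    pbc <- mean(bin == b & labels == c)
    if (pbc > 0)
      mi <- mi + pbc * log2(pbc / (mean(bin == b) * mean(labels == c)))
  }
  mi
}

# AUC by brute-force all-pairs counting
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (g in neg)
    total <- total + (p > g) + 0.5 * (p == g)
  total / (length(pos) * length(neg))
}

# hypergeometric upper tail by exhaustive enumeration of all draws of |b|
# genes from the universe
fisher_oracle <- function(universe, a, b) {
  draws <- combn(universe, length(b), simplify = FALSE)
  ov <- length(intersect(a, b))
  mean(vapply(draws, function(d) length(intersect(a, d)) >= ov, logical(1)))
}

# CORG by exhaustive scoring of every prefix of the t-ordered genes
corg_prefix_oracle <- function(ds, pathway) {
  measured <- intersect(pathway, colnames(ds$values))
  t <- sapply(measured, function(g)
    tstat(ds$values[ds$labels == 1L, g], ds$values[ds$labels == 0L, g]))
  desc <- t[which.max(abs(t))] > 0
  ord <- order(if (desc) -t else t, measured)
  measured <- measured[ord]
  # greedy stop rule: largest prefix reachable through strictly increasing |t|
  prev <- -Inf
  best_m <- 1L
  for (m in seq_along(measured)) {
    act <- activity(ds, measured[seq_len(m)])
    tm <- abs(tstat(act[ds$labels == 1L], act[ds$labels == 0L]))
    if (tm > prev) {
      prev <- tm
      best_m <- m
    } else break
  }
  list(genes = measured[seq_len(best_m)], score = prev)
}

# best MI over all connected vertex subsets of a small network
chuang_exhaustive_oracle <- function(ds, net, n_bins) {
  nodes <- intersect(net$nodes, colnames(ds$values))
  g <- igraph::graph_from_data_frame(as.data.frame(net$edges), directed = FALSE,
                                     vertices = net$nodes)
  g <- igraph::induced_subgraph(g, nodes)
  best <- 0
  for (k in seq_along(nodes)) {
    for (sub in combn(nodes, k, simplify = FALSE)) {
      sg <- igraph::induced_subgraph(g, sub)
      if (!igraph::is_connected(sg)) next
      act <- rowSums(ds$values[, sub, drop = FALSE])
      best <- max(best, mutual_information(act, ds$labels, n_bins))
    }
  }
  best
}
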
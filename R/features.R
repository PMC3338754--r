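# Feature extraction: single genes (t-statistic), mutual-information
# subnetwork search, condition-responsive gene (CORG) scoring, and hub
# correlation-difference features.  Every extractor sees only the training
# data it is handed; the resulting ranked list carries a fingerprint of its
# inputs so leakage can be asserted downstream.

#' Composite feature
#'
#' A named gene set (single gene, subnetwork, CORG set or hub neighborhood)
#' with a score and a rule for turning expression into per-sample values.
#'
#' @param name Feature name.
#' @param member_genes Ordered, non-empty character vector of gene ids.
#' @param score Real score used for ranking (|t|, mutual information, or
#'   |average hub difference| depending on `kind`).
#' @param kind One of `"single_gene"`, `"subnetwork"`, `"corg"`, `"hub"`.
#' @param hub_gene Hub gene id (`kind = "hub"` only); must be a member.
#' @return A `CompositeFeature`.
#' @export
composite_feature <- function(name, member_genes, score,
                              kind = c("single_gene", "subnetwork", "corg",
                                       "hub"),
                              hub_gene = NULL) {
  kind <- match.arg(kind)
  member_genes <- as.character(member_genes)
  if (!length(member_genes)) stopf("feature '%s' has no member genes", name)
  if (kind == "single_gene" && length(member_genes) != 1L)
    stopf("single-gene feature must have exactly one member")
  if (kind == "hub") {
    if (is.null(hub_gene) || !hub_gene %in% member_genes)
      stopf("hub feature needs hub_gene among its members")
  }
  structure(list(name = name, member_genes = member_genes,
                 score = as.numeric(score), kind = kind, hub_gene = hub_gene),
            class = "CompositeFeature")
}

#' Ranked feature list
#'
#' Features from one training set in descending score order, together with
#' the extractor name and a fingerprint of the inputs that produced it.
#'
#' @param features List of `CompositeFeature`s, scores non-increasing.
#' @param method Extractor name.
#' @param source_fingerprint Fingerprint of training data + secondary source
#'   + parameters (see [fingerprint()]).
#' @return A `RankedFeatureList`.
#' @export
ranked_feature_list <- function(features, method, source_fingerprint = "") {
  scores <- vapply(features, `[[`, numeric(1L), "score")
  if (is.unsorted(rev(scores))) stopf("scores must be non-increasing")
  structure(list(features = features, method = method,
                 source_fingerprint = source_fingerprint),
            class = "RankedFeatureList")
}

#' @export
print.RankedFeatureList <- function(x, ...) {
  cat(sprintf("RankedFeatureList (%s): %d features\n", x$method,
              length(x$features)))
  invisible(x)
}

#' @export
length.RankedFeatureList <- function(x) length(x$features)

# order features by score desc, name asc; returns the reordered list
order_features <- function(features) {
  scores <- vapply(features, `[[`, numeric(1L), "score")
  names_ <- vapply(features, `[[`, character(1L), "name")
  features[order(-scores, names_)]
}

#' Welch two-sample t-statistic
#'
#' `t = (mean(poor) - mean(good)) / sqrt(var(poor)/k1 + var(good)/k0)`;
#' positive when the poor-outcome mean is higher.
#'
#' @param values_poor,values_good Numeric vectors (each of length >= 2).
#' @return The t-statistic.
#' @export
tstat <- function(values_poor, values_good) {
  if (length(values_poor) < 2L || length(values_good) < 2L)
    stopf("each group needs at least 2 samples")
  v1 <- stats::var(values_poor)
  v0 <- stats::var(values_good)
  den <- sqrt(v1 / length(values_poor) + v0 / length(values_good))
  if (den == 0) stopf("both group variances are zero")
  (mean(values_poor) - mean(values_good)) / den
}

# vectorized per-gene t-statistics for a dataset
gene_tstats <- function(ds) {
  p <- ds$labels == 1L
  if (sum(p) < 2L || sum(!p) < 2L)
    stopf("each class needs at least 2 samples")
  vp <- ds$values[p, , drop = FALSE]
  vg <- ds$values[!p, , drop = FALSE]
  mp <- colMeans(vp); mg <- colMeans(vg)
  varp <- (colSums(vp^2) - nrow(vp) * mp^2) / (nrow(vp) - 1L)
  varg <- (colSums(vg^2) - nrow(vg) * mg^2) / (nrow(vg) - 1L)
  den <- sqrt(pmax(varp, 0) / nrow(vp) + pmax(varg, 0) / nrow(vg))
  t <- (mp - mg) / den
  t[den == 0] <- NA_real_
  t
}

#' Subnetwork / pathway activity
#'
#' Aggregates the expression of a gene set into one value per sample:
#' `a_i = sum_j e_ij / sqrt(|S|)` by default (`normalizer = "sqrt"`), or the
#' plain mean (`normalizer = "mean"`).
#'
#' @param ds An `ExpressionDataset`.
#' @param genes Character vector of member gene ids (all must be measured).
#' @param normalizer `"sqrt"` (default) or `"mean"`.
#' @return Named numeric vector, one activity per sample.
#' @export
activity <- function(ds, genes, normalizer = c("sqrt", "mean")) {
  normalizer <- match.arg(normalizer)
  miss <- setdiff(genes, gene_ids(ds))
  if (length(miss)) stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
  s <- rowSums(ds$values[, genes, drop = FALSE])
  s / switch(normalizer, sqrt = sqrt(length(genes)), mean = length(genes))
}

#' Rank single genes by |t|
#'
#' One single-gene feature per gene, scored by the absolute t-statistic
#' between the outcome classes, in descending order (ties broken by gene id).
#'
#' @param train An `ExpressionDataset`.
#' @return A `RankedFeatureList` of `single_gene` features.
#' @export
rank_single_genes <- function(train) {
  t <- gene_tstats(train)
  t[is.na(t)] <- 0
  feats <- lapply(gene_ids(train), function(g) {
    composite_feature(g, g, abs(t[[g]]), "single_gene")
  })
  ranked_feature_list(order_features(feats), "sg",
                      fingerprint(list(train$values, train$labels, "sg")))
}

default_n_bins <- function(k) floor(log2(k)) + 1L

#' Mutual information between a discretized activity and class labels
#'
#' Activities are discretized into `n_bins` equal-width bins spanning their
#' observed range; MI (in bits) is computed between the bin index and the
#' binary label.  A constant activity vector occupies a single bin and has
#' MI 0.
#'
#' @param act Numeric activity vector.
#' @param labels 0/1 labels, same length.
#' @param n_bins Number of bins (>= 2); defaults to `floor(log2(k)) + 1`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(act, labels, n_bins = default_n_bins(length(act))) {
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  if (length(act) != length(labels)) stopf("length mismatch")
  rng <- range(act)
  bin <- if (rng[1L] == rng[2L]) rep(1L, length(act)) else {
    b <- findInterval(act, seq(rng[1L], rng[2L], length.out = n_bins + 1L),
                      rightmost.closed = TRUE)
    pmin(b, n_bins)
  }
  joint <- table(factor(bin, levels = seq_len(n_bins)),
                 factor(labels, levels = c(0L, 1L))) / length(act)
  pb <- rowSums(joint); pc <- colSums(joint)
  terms <- joint * log2(joint / outer(pb, pc))
  sum(terms[is.finite(terms)])
}

#' Parameters for the mutual-information subnetwork search
#'
#' @param n_bins Bin count for the MI discretization; `NULL` means
#'   `floor(log2(k)) + 1` for k training samples.
#' @param improvement_min Minimum MI gain for the greedy search to accept a
#'   neighbor (0 = strict increase).
#' @param max_radius Maximum hop distance from the seed gene.
#' @param n_null_permutations Permutations per significance null.
#' @param alpha Significance level of the three permutation tests
#'   (`alpha = 1` disables filtering).
#' @return A `ChuangParams` list.
#' @export
chuang_params <- function(n_bins = NULL, improvement_min = 0, max_radius = 2L,
                          n_null_permutations = 1000L, alpha = 0.05) {
  structure(list(n_bins = n_bins, improvement_min = improvement_min,
                 max_radius = as.integer(max_radius),
                 n_null_permutations = as.integer(n_null_permutations),
                 alpha = alpha),
            class = "ChuangParams")
}

# nodes within `radius` hops of `seed` (including seed), given an adjacency list
bfs_ball <- function(adj, seed, radius) {
  seen <- seed
  frontier <- seed
  for (d in seq_len(radius)) {
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

# MI of the activity of a gene set (unnormalized sum; equal-width binning is
# invariant to the positive activity normalizer)
subnet_mi <- function(act_sum, labels, n_bins) {
  mutual_information(act_sum, labels, n_bins)
}

#' Greedy mutual-information subnetwork search
#'
#' Every measured network gene is used once as seed.  The subnetwork grows by
#' repeatedly adding the adjacent candidate gene (within `max_radius` hops of
#' the seed) that maximizes the mutual information between the subnetwork
#' activity and the class labels, stopping when no addition improves MI by
#' more than `improvement_min`.  Identical gene sets from different seeds are
#' deduplicated; the result is ranked by MI (descending, ties by name).
#'
#' @param train An `ExpressionDataset`.
#' @param net A `GeneNetwork` (restricted internally to measured genes).
#' @param params A `ChuangParams`.
#' @return A `RankedFeatureList` of `subnetwork` features.
#' @export
chuang_search <- function(train, net, params = chuang_params()) {
  net <- restrict_network(net, gene_ids(train))
  fp <- fingerprint(list(train$values, train$labels, net$edges, params,
                         "chuang"))
  if (!length(net$nodes))
    return(ranked_feature_list(list(), "chuang", fp))
  n_bins <- if (is.null(params$n_bins)) default_n_bins(n_samples(train))
            else params$n_bins
  adj <- adjacency_list(net)
  labels <- train$labels
  values <- train$values
  found <- new.env(parent = emptyenv())
  for (seed in sort(net$nodes)) {
    ball <- bfs_ball(adj, seed, params$max_radius)
    current <- seed
    act <- values[, seed]
    mi <- subnet_mi(act, labels, n_bins)
    repeat {
      cand <- setdiff(intersect(unique(unlist(adj[current],
                                              use.names = FALSE)), ball),
                      current)
      if (!length(cand)) break
      cand <- sort(cand)
      mis <- vapply(cand, function(g)
        subnet_mi(act + values[, g], labels, n_bins), numeric(1L))
      best <- which.max(mis)  # first max = lexicographically smallest gene
      if (mis[[best]] <= mi + params$improvement_min) break
      current <- c(current, cand[[best]])
      act <- act + values[, cand[[best]]]
      mi <- mis[[best]]
    }
    key <- paste(sort(current), collapse = "|")
    if (is.null(found[[key]]))
      found[[key]] <- composite_feature(paste0("sub:", key), sort(current),
                                        mi, "subnetwork")
  }
  feats <- order_features(as.list(found))
  ranked_feature_list(feats, "chuang", fp)
}

# grow one random connected subnetwork of size `size` (random seed, uniform
# random neighbor additions); returns its member genes
random_connected_subnetwork <- function(adj, nodes, size) {
  current <- sample(nodes, 1L)
  while (length(current) < size) {
    cand <- setdiff(unique(unlist(adj[current], use.names = FALSE)), current)
    if (!length(cand)) break
    current <- c(current, sample(cand, 1L))
  }
  current
}

#' Permutation significance filter for subnetwork features
#'
#' Keeps only features whose mutual information exceeds the
#' `100 * (1 - alpha)` percentile of three permutation nulls: (1) MI of
#' random connected subnetworks of the same size grown from random seeds;
#' (2) MI after permuting the gene-to-node assignment (random gene sets of
#' the same size); (3) MI of the feature's own activity against permuted
#' class labels.
#'
#' @param feats A `RankedFeatureList` from [chuang_search()].
#' @param train The same training `ExpressionDataset`.
#' @param net The same `GeneNetwork`.
#' @param params A `ChuangParams` (permutation count and alpha).
#' @param seed Integer seed for the permutation draws; derived from the
#'   input fingerprint when `NULL`.
#' @return The filtered `RankedFeatureList`.
#' @export
chuang_significance_filter <- function(feats, train, net,
                                       params = chuang_params(),
                                       seed = NULL) {
  if (params$alpha >= 1 || !length(feats$features)) return(feats)
  net <- restrict_network(net, gene_ids(train))
  if (is.null(seed)) seed <- seed_from_fingerprint(feats$source_fingerprint)
  n_bins <- if (is.null(params$n_bins)) default_n_bins(n_samples(train))
            else params$n_bins
  adj <- adjacency_list(net)
  labels <- train$labels
  values <- train$values
  genes <- gene_ids(train)
  nperm <- params$n_null_permutations
  q <- 1 - params$alpha
  sizes <- sort(unique(vapply(feats$features, function(f)
    length(f$member_genes), integer(1L))))
  with_seed(seed, {
    thr_subnet <- thr_geneset <- stats::setNames(numeric(length(sizes)),
                                                 sizes)
    for (s in sizes) {
      mi_rand <- vapply(seq_len(nperm), function(i) {
        g <- random_connected_subnetwork(adj, net$nodes, s)
        subnet_mi(rowSums(values[, g, drop = FALSE]), labels, n_bins)
      }, numeric(1L))
      thr_subnet[[as.character(s)]] <- stats::quantile(mi_rand, q,
                                                       names = FALSE)
      mi_gene <- vapply(seq_len(nperm), function(i) {
        g <- sample(genes, s)
        subnet_mi(rowSums(values[, g, drop = FALSE]), labels, n_bins)
      }, numeric(1L))
      thr_geneset[[as.character(s)]] <- stats::quantile(mi_gene, q,
                                                        names = FALSE)
    }
    label_perms <- replicate(nperm, sample(labels), simplify = FALSE)
    keep <- vapply(feats$features, function(f) {
      s <- as.character(length(f$member_genes))
      if (f$score <= thr_subnet[[s]] || f$score <= thr_geneset[[s]])
        return(FALSE)
      act <- rowSums(values[, f$member_genes, drop = FALSE])
      mi_null <- vapply(label_perms, function(l)
        subnet_mi(act, l, n_bins), numeric(1L))
      f$score > stats::quantile(mi_null, q, names = FALSE)
    }, logical(1L))
    ranked_feature_list(feats$features[keep], feats$method,
                        feats$source_fingerprint)
  })
}

#' Condition-responsive genes (CORG) of one pathway
#'
#' Orders the measured pathway genes by their t-statistic (descending when
#' the largest-|t| gene has positive t, ascending otherwise) and greedily
#' extends the prefix while the t-statistic of the averaged activity strictly
#' increases in absolute value.  The feature's score is the final |t| of the
#' prefix activity.
#'
#' @param train An `ExpressionDataset`.
#' @param pathway_genes Character vector of pathway gene ids.
#' @param name Feature name.
#' @return A `CompositeFeature` of kind `corg`, or `NULL` (with a message)
#'   when no pathway gene is measured.
#' @export
lee_corg <- function(train, pathway_genes, name = "corg") {
  measured <- intersect(pathway_genes, gene_ids(train))
  if (!length(measured)) {
    message(sprintf("pathway '%s': no measured genes, skipped", name))
    return(NULL)
  }
  t <- gene_tstats(train)[measured]
  t[is.na(t)] <- 0
  top_positive <- t[[which.max(abs(t))]] > 0
  ord <- order(if (top_positive) -t else t, measured)
  measured <- measured[ord]
  labels <- train$labels
  prefix <- measured[[1L]]
  best_t <- tstat(train$values[labels == 1L, prefix],
                  train$values[labels == 0L, prefix])
  for (m in seq_along(measured)[-1L]) {
    act <- activity(train, measured[seq_len(m)])
    t_m <- tstat(act[labels == 1L], act[labels == 0L])
    if (abs(t_m) > abs(best_t)) {
      prefix <- measured[seq_len(m)]
      best_t <- t_m
    } else break
  }
  composite_feature(name, prefix, abs(best_t), "corg")
}

#' Rank pathways by their CORG score
#'
#' Builds one CORG feature per gene set and ranks them by score
#' (descending); by default all sets are kept unless the collection holds
#' more than 400 sets, in which case the top 400 are returned.
#'
#' @param train An `ExpressionDataset`.
#' @param coll A `GeneSetCollection`.
#' @param top_k Number of top pathways to keep (`NULL` = all, capped at 400
#'   for larger collections).
#' @return A `RankedFeatureList` of `corg` features.
#' @export
lee_rank_pathways <- function(train, coll, top_k = NULL) {
  fp <- fingerprint(list(train$values, train$labels, coll$sets, top_k, "lee"))
  feats <- list()
  for (nm in sort(names(coll$sets)))
    feats[[nm]] <- lee_corg(train, coll$sets[[nm]], name = nm)
  feats <- order_features(feats[!vapply(feats, is.null, logical(1L))])
  if (is.null(top_k)) top_k <- if (length(coll$sets) > 400L) 400L else
    length(feats)
  ranked_feature_list(utils::head(feats, top_k), "lee", fp)
}

#' Pearson correlation with degenerate-input guard
#'
#' Plain Pearson correlation; when either vector has zero variance the
#' correlation is undefined and 0 is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector in correlation; using 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Hub difference and average hub difference
#'
#' `hub_difference` is the Pearson correlation between hub and interactor
#' expression within the poor class minus the same correlation within the
#' good class; `avg_hub_difference` averages it over the hub's (measured)
#' neighbors.
#'
#' @param train An `ExpressionDataset`; each class needs >= 3 samples.
#' @param hub Hub gene id.
#' @param interactor Interactor gene id.
#' @param neighbors Character vector of interactor gene ids.
#' @return A real in `[-2, 2]`.
#' @export
hub_difference <- function(train, hub, interactor) {
  p <- train$labels == 1L
  if (sum(p) < 3L || sum(!p) < 3L)
    stopf("each class needs at least 3 samples for correlations")
  h <- train$values[, hub]; n <- train$values[, interactor]
  pearson(h[p], n[p]) - pearson(h[!p], n[!p])
}

#' @rdname hub_difference
#' @export
avg_hub_difference <- function(train, hub, neighbors) {
  mean(vapply(neighbors, function(g) hub_difference(train, hub, g),
              numeric(1L)))
}

#' Parameters for the hub correlation-difference extractor
#'
#' @param hub_fraction Fraction of most densely connected network nodes
#'   considered candidate hubs (ties at the cutoff included).
#' @param n_label_permutations Label permutations for the hub p-value.
#' @param alpha P-value cutoff for keeping a hub.
#' @return A `TaylorParams` list.
#' @export
taylor_params <- function(hub_fraction = 0.15, n_label_permutations = 1000L,
                          alpha = 0.05) {
  structure(list(hub_fraction = hub_fraction,
                 n_label_permutations = as.integer(n_label_permutations),
                 alpha = alpha),
            class = "TaylorParams")
}

# class-conditional correlation difference of a hub against a neighbor
# matrix, vectorized over neighbors; degenerate correlations contribute 0
corr_diff_vec <- function(h, nb, labels) {
  cls_cor <- function(idx) {
    suppressWarnings(r <- stats::cor(h[idx], nb[idx, , drop = FALSE]))
    r[!is.finite(r)] <- 0
    r
  }
  as.numeric(cls_cor(labels == 1L) - cls_cor(labels == 0L))
}

#' Significant hubs by average correlation difference
#'
#' Candidate hubs are the top `hub_fraction` of nodes by degree in the full
#' network (before expression filtering, ties at the cutoff included).  For
#' each measured candidate with at least one measured neighbor, the average
#' hub difference over its measured neighbors is compared against a
#' label-permutation null; hubs with empirical `p < alpha` are kept, ranked
#' by |average hub difference|.  Each kept hub becomes one feature whose
#' members are the hub plus its measured neighbors.
#'
#' @param train An `ExpressionDataset`.
#' @param net A `GeneNetwork` (full universe).
#' @param params A `TaylorParams`.
#' @param seed Seed for the label permutations; derived from the inputs when
#'   `NULL`.
#' @return A `RankedFeatureList` of `hub` features.
#' @export
taylor_significant_hubs <- function(train, net, params = taylor_params(),
                                    seed = NULL) {
  fp <- fingerprint(list(train$values, train$labels, net$edges, params,
                         "taylor"))
  deg <- network_degrees(net)
  if (!length(deg)) return(ranked_feature_list(list(), "taylor", fp))
  k_cand <- max(1L, ceiling(params$hub_fraction * length(deg)))
  cutoff <- sort(deg, decreasing = TRUE)[[k_cand]]
  candidates <- sort(names(deg)[deg >= cutoff & deg > 0L])
  adj <- adjacency_list(net)
  measured <- gene_ids(train)
  labels <- train$labels
  if (sum(labels == 1L) < 3L || sum(labels == 0L) < 3L)
    stopf("each class needs at least 3 samples for correlations")
  if (is.null(seed)) seed <- seed_from_fingerprint(fp)
  nperm <- params$n_label_permutations
  feats <- with_seed(seed, {
    label_perms <- replicate(nperm, sample(labels), simplify = FALSE)
    out <- list()
    for (hub in candidates) {
      if (!hub %in% measured) next
      nbrs <- intersect(adj[[hub]], measured)
      if (!length(nbrs)) next
      h <- train$values[, hub]
      nb <- train$values[, nbrs, drop = FALSE]
      obs <- mean(corr_diff_vec(h, nb, labels))
      null <- vapply(label_perms, function(l)
        mean(corr_diff_vec(h, nb, l)), numeric(1L))
      p <- mean(abs(null) >= abs(obs))
      if (p < params$alpha)
        out[[hub]] <- composite_feature(paste0("hub:", hub),
                                        c(hub, nbrs), abs(obs), "hub",
                                        hub_gene = hub)
    }
    out
  })
  ranked_feature_list(order_features(feats), "taylor", fp)
}

#' Per-sample values of a composite feature
#'
#' Single genes map to their expression column; subnetwork and CORG features
#' map to the activity of their members; hub features contribute one column
#' per hub-interactor edge, holding `e(hub) - e(interactor)`.
#'
#' @param ds An `ExpressionDataset`.
#' @param feature A `CompositeFeature`.
#' @param normalizer Activity normalizer, see [activity()].
#' @return A samples x dimensions numeric matrix with provenance column
#'   names.
#' @export
feature_values <- function(ds, feature, normalizer = "sqrt") {
  switch(feature$kind,
    single_gene = {
      m <- ds$values[, feature$member_genes, drop = FALSE]
      colnames(m) <- feature$name
      m
    },
    subnetwork = ,
    corg = {
      m <- matrix(activity(ds, feature$member_genes, normalizer), ncol = 1L,
                  dimnames = list(sample_ids(ds), feature$name))
      m
    },
    hub = {
      nbrs <- setdiff(feature$member_genes, feature$hub_gene)
      m <- ds$values[, feature$hub_gene] - ds$values[, nbrs, drop = FALSE]
      colnames(m) <- paste0(feature$name, ":", nbrs)
      m
    })
}

#' Feature matrix for a set of ranked features
#'
#' Concatenates [feature_values()] columns for the first `n` features of a
#' ranked list.  A hub feature contributes as many columns as it has
#' measured interactors.
#'
#' @param ds An `ExpressionDataset`.
#' @param feats A `RankedFeatureList` (or list of `CompositeFeature`s).
#' @param n Number of top features to use (default: all).
#' @return A list with `values` (samples x dimensions matrix), `provenance`
#'   (column names) and `labels`.
#' @export
feature_matrix <- function(ds, feats, n = NULL) {
  features <- if (inherits(feats, "RankedFeatureList")) feats$features
              else feats
  if (!is.null(n)) features <- features[seq_len(min(n, length(features)))]
  if (!length(features)) stopf("no features to build a matrix from")
  cols <- lapply(features, function(f) feature_values(ds, f))
  values <- do.call(cbind, cols)
  structure(list(values = values, provenance = colnames(values),
                 labels = ds$labels),
            class = "FeatureMatrix")
}

# memoisation of extraction results: extraction is a pure function of
# (training data, secondary source, parameters), so repeated calls with the
# same inputs -- e.g. one training cohort tested against several test
# cohorts -- reuse the ranked list
.extract_cache <- new.env(parent = emptyenv())

#' Extract features with any of the four methods
#'
#' Dispatcher used by the evaluation protocol: `"sg"` ranks single genes,
#' `"chuang"` runs the subnetwork search plus significance filter,
#' `"lee"` ranks pathways by CORG score, `"taylor"` finds significant hubs.
#' Results are memoised on a fingerprint of the inputs.
#'
#' @param train Training `ExpressionDataset` (the only data the extractor
#'   sees).
#' @param method One of `"sg"`, `"chuang"`, `"lee"`, `"taylor"`.
#' @param secondary A `GeneNetwork` (chuang/taylor) or `GeneSetCollection`
#'   (lee); ignored for `"sg"`.
#' @param params Method parameter object (`chuang_params()` /
#'   `taylor_params()`; for `"lee"` a list with optional `top_k`).
#' @return A `RankedFeatureList`.
#' @export
extract_features <- function(train, method = c("sg", "chuang", "lee",
                                               "taylor"),
                             secondary = NULL, params = NULL) {
  method <- match.arg(method)
  key <- fingerprint(list(train$values, train$labels, method,
                          if (inherits(secondary, "GeneNetwork"))
                            secondary$edges
                          else if (inherits(secondary, "GeneSetCollection"))
                            secondary$sets,
                          params))
  if (!is.null(.extract_cache[[key]])) return(.extract_cache[[key]])
  res <- extract_features_impl(train, method, secondary, params)
  if (length(ls(.extract_cache)) > 200L)
    rm(list = ls(.extract_cache), envir = .extract_cache)
  .extract_cache[[key]] <- res
  res
}

extract_features_impl <- function(train, method, secondary, params) {
  switch(method,
    sg = rank_single_genes(train),
    chuang = {
      if (is.null(params)) params <- chuang_params()
      feats <- chuang_search(train, secondary, params)
      chuang_significance_filter(feats, train, secondary, params)
    },
    lee = lee_rank_pathways(train, secondary,
                            top_k = if (!is.null(params)) params$top_k),
    taylor = taylor_significant_hubs(train, secondary,
                                     params %||% taylor_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
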
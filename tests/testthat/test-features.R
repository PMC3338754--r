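# Feature extraction: t-statistics, activity, mutual information, the
# greedy subnetwork search, CORG scoring, hub differences and feature
# values.

test_that("tstat matches the hand-computed Welch form and its symmetries", {
  expect_equal(tstat(c(4, 5, 6), c(1, 2, 3)), 3 / sqrt(2 / 3))
  expect_equal(tstat(c(4, 5, 6), c(1, 2, 3)), 3.674235, tolerance = 1e-6)
  expect_equal(tstat(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(tstat(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3))
  expect_error(tstat(c(1), c(1, 2)), "at least 2")
  expect_error(tstat(c(2, 2, 2), c(5, 5)), "variances")
})

test_that("activity follows the sqrt-normalized sum with a mean option", {
  ds <- expression_dataset(matrix(c(1, 2, -1, 2), 2, 2,
                                  dimnames = list(c("s1", "s2"),
                                                  c("g1", "g2"))),
                           labels = c(0, 1))
  a <- activity(ds, c("g1", "g2"))
  expect_equal(unname(a), c(0, 4 / sqrt(2)))
  expect_equal(unname(a[2]), 2.8284, tolerance = 1e-4)
  expect_equal(activity(ds, "g1"), ds$values[, "g1"])
  expect_equal(unname(activity(ds, c("g1", "g2"), "mean")), c(0, 2))
  expect_error(activity(ds, "nope"), "unknown gene")
})

test_that("mutual information reproduces hand cases and the binary bound", {
  expect_equal(mutual_information(c(-1, -1, 1, 1), c(0, 0, 1, 1), 2), 1)
  expect_equal(mutual_information(c(-1, 1, -1, 1), c(0, 0, 1, 1), 2), 0)
  expect_equal(mutual_information(rep(3, 6), c(0, 1, 0, 1, 0, 1), 4), 0)
  set.seed(1)
  for (i in 1:25) {
    act <- rnorm(30)
    lab <- rbinom(30, 1, 0.4)
    if (length(unique(lab)) < 2) next
    nb <- sample(2:6, 1)
    mi <- mutual_information(act, lab, nb)
    expect_gte(mi, 0)
    expect_lte(mi, min(log2(nb), 1) + 1e-12)
    expect_equal(mi, mi_oracle(act, lab, nb), tolerance = 1e-12)
  }
})

test_that("single-gene ranking is |t|-descending with lexicographic ties", {
  ds <- make_toy_dataset(n = 60, n_genes = 8, effect = 3, informative = 5)
  feats <- rank_single_genes(ds)
  expect_identical(feats$features[[1]]$name, "g005")
  scores <- vapply(feats$features, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
  # duplicated column => identical scores, adjacent, id order
  v <- ds$values
  v[, "g002"] <- v[, "g007"]
  dup <- expression_dataset(v, ds$labels)
  nm <- vapply(rank_single_genes(dup)$features, `[[`, character(1), "name")
  expect_equal(which(nm == "g007") - which(nm == "g002"), 1)
})

test_that("extractors are invariant to sample and gene order", {
  ds <- make_toy_dataset(n = 30, n_genes = 6)
  perm_s <- sample(nrow(ds$values))
  perm_g <- sample(ncol(ds$values))
  ds2 <- expression_dataset(ds$values[perm_s, perm_g], ds$labels[perm_s])
  f1 <- rank_single_genes(ds)
  f2 <- rank_single_genes(ds2)
  expect_identical(lapply(f1$features, `[`, c("name", "score")),
                   lapply(f2$features, `[`, c("name", "score")))
})

test_that("greedy subnetwork search keeps a dominant star center alone", {
  set.seed(8)
  n <- 40
  labels <- rep(c(1L, 0L), each = n / 2)
  values <- cbind(g1 = labels * 3 + rnorm(n, sd = 0.1),
                  matrix(rnorm(n * 4), n, 4,
                         dimnames = list(NULL, paste0("g", 2:5))))
  rownames(values) <- paste0("s", 1:n)
  ds <- expression_dataset(values, labels)
  net <- gene_network(cbind("g1", paste0("g", 2:5)))
  feats <- chuang_search(ds, net, chuang_params())
  top <- feats$features[[1]]
  expect_identical(top$member_genes, "g1")
  # greedy equals the exhaustive optimum here
  expect_equal(top$score,
               chuang_exhaustive_oracle(ds, net,
                                        cfbench:::default_n_bins(n)))
})

test_that("disconnected genes are never merged into one subnetwork", {
  ds <- make_toy_dataset(n = 30, n_genes = 4, effect = 3, informative = 1:2)
  net <- gene_network(matrix(character(), ncol = 2),
                      nodes = c("g001", "g002"))
  feats <- chuang_search(ds, net, chuang_params())
  expect_equal(length(feats), 2)
  expect_true(all(vapply(feats$features, function(f)
    length(f$member_genes), integer(1)) == 1))
})

test_that("subnetwork search is deterministic under node-order permutation", {
  ds <- make_toy_dataset(n = 30, n_genes = 8, informative = c(2, 5))
  edges <- rbind(c("g002", "g001"), c("g002", "g003"), c("g003", "g005"),
                 c("g005", "g007"), c("g004", "g006"), c("g006", "g008"))
  f1 <- chuang_search(ds, gene_network(edges), chuang_params())
  f2 <- chuang_search(ds, gene_network(edges[sample(nrow(edges)), 2:1]),
                      chuang_params())
  expect_identical(lapply(f1$features, `[`, c("name", "score")),
                   lapply(f2$features, `[`, c("name", "score")))
})

test_that("greedy subnetwork MI never beats the exhaustive optimum", {
  for (seed in 1:4) {
    set.seed(seed)
    n_genes <- 8
    g <- igraph::sample_gnp(n_genes, 0.35)
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) next
    ids <- sprintf("g%03d", 1:n_genes)
    net <- gene_network(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
    ds <- make_toy_dataset(n = 24, n_genes = n_genes, effect = 1.5,
                           seed = seed, informative = 1:2)
    feats <- chuang_search(ds, net, chuang_params(max_radius = n_genes))
    best_greedy <- max(vapply(feats$features, `[[`, numeric(1), "score"))
    best_exact <- chuang_exhaustive_oracle(ds, net,
                                           cfbench:::default_n_bins(24))
    expect_lte(best_greedy, best_exact + 1e-12)
  }
})

test_that("the significance filter is the identity at alpha = 1 and keeps a planted module", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 80,
                           n_genes = 80, n_informative = 6,
                           effect_size = 2, planted_module_sizes = 6,
                           corr_flip_module = NA, n_genesets = 5,
                           geneset_size_range = c(5, 8), seed = 13)
  b <- simulate_benchmark(cfg)
  ds <- b$cohorts[[1]]
  p <- chuang_params(n_null_permutations = 100)
  feats <- chuang_search(ds, b$network, p)
  p1 <- p; p1$alpha <- 1
  expect_identical(chuang_significance_filter(feats, ds, b$network, p1),
                   feats)
  kept <- chuang_significance_filter(feats, ds, b$network, p)
  expect_gt(length(kept), 0)
  # the top surviving subnetwork overlaps the planted module
  expect_gt(length(intersect(kept$features[[1]]$member_genes,
                             b$truth$modules[[1]])), 0)
})

test_that("lee_corg matches the prefix-exhaustive oracle", {
  set.seed(5)
  n <- 50
  labels <- rep(c(1L, 0L), each = 25)
  # three independent strongly-up genes: averaging raises |t|
  values <- sapply(1:3, function(i) labels * 1.5 + rnorm(n))
  colnames(values) <- paste0("up", 1:3)
  more <- matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("n", 1:9)))
  ds <- expression_dataset(cbind(values, more), labels)
  corg <- lee_corg(ds, paste0("up", 1:3), "p3")
  expect_setequal(corg$member_genes, paste0("up", 1:3))
  oracle <- corg_prefix_oracle(ds, paste0("up", 1:3))
  expect_identical(corg$member_genes, oracle$genes)
  expect_equal(corg$score, oracle$score)
  # one informative + noise: the noise genes are not worth averaging in
  corg2 <- lee_corg(ds, c("up1", paste0("n", 1:9)), "p10")
  oracle2 <- corg_prefix_oracle(ds, c("up1", paste0("n", 1:9)))
  expect_identical(corg2$member_genes, oracle2$genes)
  expect_equal(corg2$score, oracle2$score)
  # single-gene pathway: score is that gene's |t|
  corg1 <- lee_corg(ds, "up2", "p1")
  expect_identical(corg1$member_genes, "up2")
  expect_equal(corg1$score,
               abs(tstat(ds$values[labels == 1, "up2"],
                         ds$values[labels == 0, "up2"])))
  # greedy never accepts a worsening step
  for (i in 1:5) {
    pw <- sample(colnames(ds$values), 6)
    t <- abs(sapply(pw, function(g)
      tstat(ds$values[labels == 1, g], ds$values[labels == 0, g])))
    expect_gte(lee_corg(ds, pw)$score, max(t) - 1e-12)
  }
})

test_that("pathway ranking puts a planted set first and ignores name order", {
  ds <- make_toy_dataset(n = 60, n_genes = 20, effect = 2, informative = 1:4)
  sets <- list(planted = sprintf("g%03d", 1:4),
               noiseA = sprintf("g%03d", 11:15),
               noiseB = sprintf("g%03d", 16:20))
  r1 <- lee_rank_pathways(ds, gene_set_collection(sets))
  expect_identical(r1$features[[1]]$name, "planted")
  r2 <- lee_rank_pathways(ds, gene_set_collection(rev(sets)))
  expect_identical(lapply(r1$features, `[`, c("name", "score")),
                   lapply(r2$features, `[`, c("name", "score")))
  expect_length(lee_rank_pathways(ds, gene_set_collection(list())), 0)
  # unmeasured pathway is skipped with a message, not an error
  expect_message(
    r3 <- lee_rank_pathways(ds, gene_set_collection(list(gone = "zzz",
                                                         planted = sets$planted))),
    "skipped")
  expect_length(r3, 1)
})

test_that("pearson handles the hand case and degenerate input", {
  expect_equal(pearson(1:3, 1:3), 1)
  expect_equal(pearson(1:3, -(1:3)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_warning(r <- pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r, 0)
})

test_that("hub difference and its average follow the correlation contrast", {
  h <- c(1, 2, 3, 1, 2, 3)
  labels <- c(0, 0, 0, 1, 1, 1)
  values <- cbind(hub = h, flip = c(1, 2, 3, 3, 2, 1), same = h)
  rownames(values) <- paste0("s", 1:6)
  ds <- expression_dataset(values, labels)
  expect_equal(hub_difference(ds, "hub", "flip"), -2)
  expect_equal(hub_difference(ds, "hub", "same"), 0)
  expect_equal(avg_hub_difference(ds, "hub", c("flip", "same")), -1)
  small <- expression_dataset(values[1:4, ], labels = c(0, 0, 1, 1))
  expect_error(hub_difference(small, "hub", "flip"), "3 samples")
})

test_that("hub candidates include degree ties and drop unmeasured neighborhoods", {
  # degree: h1 = 3, h2 = 3 (tie at cutoff), rest lower; h2's neighbors are
  # unmeasured proteins
  edges <- rbind(c("h1", "a"), c("h1", "b"), c("h1", "c"),
                 c("h2", "u1"), c("h2", "u2"), c("h2", "u3"),
                 c("a", "b"))
  net <- gene_network(edges)
  set.seed(2)
  n <- 30
  labels <- rep(c(0L, 1L), each = 15)
  measured <- c("h1", "h2", "a", "b", "c")
  values <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, measured))
  # make h1-a correlation flip with class
  values[, "a"] <- ifelse(labels == 1, -1, 1) * values[, "h1"] +
    rnorm(n, sd = 0.2)
  ds <- expression_dataset(values, labels)
  feats <- taylor_significant_hubs(ds, net,
                                   taylor_params(hub_fraction = 0.15,
                                                 n_label_permutations = 200))
  hubs <- vapply(feats$features, `[[`, character(1), "hub_gene")
  expect_true("h1" %in% hubs)   # detected flip
  expect_false("h2" %in% hubs)  # no measured neighbors
})

test_that("feature values map kinds to columns as documented", {
  values <- rbind(s1 = c(h = 2, n1 = 0.5, n2 = -1),
                  s2 = c(h = 0, n1 = 0, n2 = 0))
  ds <- expression_dataset(values, labels = c(1, 0))
  hub <- composite_feature("hub:h", c("h", "n1", "n2"), 1, "hub",
                           hub_gene = "h")
  fv <- feature_values(ds, hub)
  expect_equal(unname(fv["s1", ]), c(1.5, 3.0))
  expect_equal(colnames(fv), c("hub:h:n1", "hub:h:n2"))
  sg <- composite_feature("h", "h", 1, "single_gene")
  expect_equal(unname(feature_values(ds, sg)[, 1]), unname(values[, "h"]))
  corg <- composite_feature("c", "n1", 1, "corg")
  expect_equal(unname(feature_values(ds, corg)[, 1]), unname(values[, "n1"]))
})

test_that("ranked lists are fingerprinted and ignore unrelated data", {
  train <- make_toy_dataset(n = 30, n_genes = 6, seed = 1)
  test <- make_toy_dataset(n = 20, n_genes = 6, seed = 2)
  f1 <- extract_features(train, "sg")
  test$values[] <- rnorm(length(test$values))  # perturb the test set
  f2 <- extract_features(train, "sg")
  expect_identical(f1, f2)
  # changing the training data changes the fingerprint
  train$values[1, 1] <- train$values[1, 1] + 1
  f3 <- extract_features(train, "sg")
  expect_false(identical(f1$source_fingerprint, f3$source_fingerprint))
})
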
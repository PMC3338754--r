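# Cross-validation protocol, the three evaluation settings, win/loss
# matrix and paired Wilcoxon comparisons.

eval_rec_stub <- function(method, src, aucs) {
  data.frame(method = method, secondary_source = src,
             classifier_kind = "nmc",
             train_name = paste0("t", seq_along(aucs)),
             test_name = paste0("v", seq_along(aucs)),
             n_features_policy = "fixed_5", n_features_used = 5,
             auc = aucs, feasible = TRUE, converged = TRUE,
             stringsAsFactors = FALSE)
}

make_cohorts <- function(n_cohorts, n = 40, effect = 2, seed = 100,
                         n_genes = 12) {
  lapply(seq_len(n_cohorts), function(i)
    make_toy_dataset(n = n, n_genes = n_genes, effect = effect,
                     seed = seed + i, name = paste0("d", i)))
}

test_that("cv_select_n picks a feature count reproducibly", {
  ds <- make_toy_dataset(n = 50, n_genes = 8, effect = 2.5)
  sel <- cv_select_n(ds, "sg", clf_kind = "nmc", grid = c(1, 3, 5))
  expect_true(sel$n %in% c(1, 3, 5))
  expect_gt(sel$mean_auc, 0.9)
  # grid of size one returns that value
  expect_equal(cv_select_n(ds, "sg", grid = 3)$n, 3)
  # permuting sample order leaves the selection unchanged
  perm <- sample(nrow(ds$values))
  ds2 <- expression_dataset(ds$values[perm, ], ds$labels[perm], name = ds$name)
  sel2 <- cv_select_n(ds2, "sg", clf_kind = "nmc", grid = c(1, 3, 5))
  expect_identical(sel$n, sel2$n)
  expect_equal(sel$curve, sel2$curve)
})

test_that("train_and_test refuses train == test and flags infeasible fixed k", {
  ds <- make_cohorts(2)
  expect_error(train_and_test(ds[[1]], ds[[1]], "sg"), "must differ")
  expect_message(rec <- train_and_test(ds[[1]], ds[[2]], "sg",
                                       policy = "fixed_50"),
                 "infeasible")
  expect_false(rec$feasible)
  expect_true(is.na(rec$auc))
  rec2 <- train_and_test(ds[[1]], ds[[2]], "sg", policy = "fixed_5")
  expect_equal(rec2$n_features_used, 5)
  expect_true(rec2$auc >= 0 && rec2$auc <= 1)
})

test_that("a null cohort pair yields chance-level AUC", {
  ds <- make_cohorts(2, n = 60, effect = 0, seed = 500)
  rec <- train_and_test(ds[[1]], ds[[2]], "sg", policy = "fixed_5")
  expect_gt(rec$auc, 0.3)
  expect_lt(rec$auc, 0.7)
})

test_that("paired setting yields D(D-1) records and respects bounds", {
  ds <- make_cohorts(3)
  rec <- paired_setting(ds, method = "sg", policy = "fixed_5")
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$train_name != rec$test_name))
  expect_true(all(rec$auc >= 0 & rec$auc <= 1))
  expect_equal(nrow(paired_setting(ds[1:2], method = "sg",
                                   policy = "fixed_5")), 2)
  expect_equal(nrow(paired_setting(ds[1], method = "sg",
                                   policy = "fixed_5")), 0)
})

test_that("merged setting pools all-but-one cohort", {
  ds <- make_cohorts(3, n = 30)
  rec <- merged_setting(ds, method = "sg", policy = "fixed_5")
  expect_equal(nrow(rec), 3)
  expect_true(all(startsWith(rec$train_name, "merged_wo_")))
})

test_that("ER stratification filters before pooling and normalization", {
  ds <- make_cohorts(3, n = 40)
  for (i in seq_along(ds)) {
    set.seed(i)
    ds[[i]]$er_status <- rbinom(40, 1, 0.7)
  }
  rec <- er_stratified_setting(ds, method = "sg", policy = "fixed_5")
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$feasible))
  # a cohort without ER-positive cases produces an infeasibility record
  ds[[2]]$er_status <- rep(0L, 40)
  expect_message(rec2 <- er_stratified_setting(ds, method = "sg",
                                               policy = "fixed_5"),
                 "not evaluable")
  expect_equal(nrow(rec2), 3)
  expect_false(rec2$feasible[2])
  # order of operations: the ER-positive pool itself is mean-zero
  pool <- merge_datasets(lapply(ds[c(1, 3)], function(d)
    cfbench:::subset_samples(d, d$er_status == 1L)))
  expect_lt(max(abs(colMeans(pool$values))), 1e-12)
})

test_that("win/loss matrix is antisymmetric with smoothed log ratios", {
  recs <- rbind(
    eval_rec_stub("m1", "s", c(0.9, 0.8, 0.7)),
    eval_rec_stub("m2", "s", c(0.5, 0.6, 0.4)))
  m <- win_loss(recs)
  expect_equal(m["m1/s", "m2/s"], log2(4 / 1))
  expect_equal(m, -t(m))
  expect_equal(diag(m), c("m1/s" = 0, "m2/s" = 0))
  # identical AUCs everywhere: draws only, all-zero matrix
  recs2 <- rbind(eval_rec_stub("m1", "s", c(0.5, 0.5)),
                 eval_rec_stub("m2", "s", c(0.5, 0.5)))
  expect_true(all(win_loss(recs2) == 0))
  # random records stay antisymmetric
  set.seed(3)
  recs3 <- do.call(rbind, lapply(paste0("m", 1:4), function(m)
    eval_rec_stub(m, "s", runif(6))))
  expect_equal(win_loss(recs3), -t(win_loss(recs3)))
})

test_that("paired Wilcoxon comparisons behave at the boundaries", {
  x <- seq(0.5, 0.8, length.out = 30)
  expect_equal(compare_methods(x, x)$p_value, 1)
  up <- compare_methods(x + 0.05, x, alternative = "greater")
  expect_lt(up$p_value, 1e-6)
  down <- compare_methods(x, x + 0.05, alternative = "greater")
  expect_gt(down$p_value, 0.999)
  # sides are antisymmetric for tie-free differences
  set.seed(9)
  y <- x + rnorm(30, 0, 0.03)
  g <- compare_methods(x, y, alternative = "greater")$p_value
  l <- compare_methods(y, x, alternative = "less")$p_value
  expect_equal(g, l)
  expect_equal(compare_methods(x + 0.05, x, n_comparisons = 10)$p_adjusted,
               min(1, compare_methods(x + 0.05, x)$p_value * 10))
})

test_that("the leakage guard holds end to end", {
  ds <- make_cohorts(2, n = 50, n_genes = 10)
  train <- ds[[1]]
  test1 <- ds[[2]]
  test2 <- ds[[2]]
  set.seed(77)
  test2$values[] <- rnorm(length(test2$values))  # pure noise test set
  feats1 <- extract_features(train, "sg")
  sel1 <- cv_select_n(train, "sg", grid = c(2, 4))
  feats2 <- extract_features(train, "sg")
  sel2 <- cv_select_n(train, "sg", grid = c(2, 4))
  expect_identical(feats1, feats2)
  expect_identical(sel1, sel2)
  clf1 <- train_classifier(feature_matrix(train, feats1, sel1$n), "nmc")
  clf2 <- train_classifier(feature_matrix(train, feats2, sel2$n), "nmc")
  expect_identical(clf1, clf2)
})
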
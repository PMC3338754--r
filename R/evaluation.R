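# Leakage-free cross-dataset evaluation: inner 5-fold CV to pick the number
# of features, train on the full training cohort, test once on an untouched
# test cohort.  Settings: paired (all ordered cohort pairs), merged
# (leave-one-cohort-out pooling) and ER-stratified merged.

# content fingerprint that is independent of sample row order
canonical_fingerprint <- function(ds, extra = NULL) {
  ord <- order(sample_ids(ds))
  fingerprint(list(ds$values[ord, , drop = FALSE], ds$labels[ord], extra))
}

# stratified fold assignment by sample id, reproducible and row-order
# independent: samples of each class are shuffled (seeded) in sorted-id
# order and dealt round-robin over folds
stratified_folds <- function(ds, n_folds, seed) {
  ids <- sample_ids(ds)
  fold <- stats::setNames(integer(length(ids)), ids)
  with_seed(seed, for (cls in c(0L, 1L)) {
    cls_ids <- sort(ids[ds$labels == cls])
    cls_ids <- sample(cls_ids)
    fold[cls_ids] <- rep_len(seq_len(n_folds), length(cls_ids))
  })
  fold[ids]
}

# per-feature column index blocks of a feature matrix, so classifiers over
# the top-n features reuse one materialized matrix
feature_col_blocks <- function(ds, feats) {
  widths <- vapply(feats$features, function(f)
    ncol(feature_values(ds, f)), integer(1L))
  starts <- utils::head(cumsum(c(0L, widths)), -1L) + 1L
  mapply(function(s, w) seq(s, length.out = w), starts, widths,
         SIMPLIFY = FALSE)
}

subset_feature_matrix <- function(fm, cols) {
  structure(list(values = fm$values[, cols, drop = FALSE],
                 provenance = fm$provenance[cols], labels = fm$labels),
            class = "FeatureMatrix")
}

#' Select the number of features by inner cross-validation
#'
#' Splits the training cohort into stratified folds (fold assignment seeded
#' from a content hash of the training data, so it does not depend on input
#' row order), extracts and ranks features on each fold's training part
#' only, trains a classifier series over the feature-count grid and scores
#' the held-out part by AUC.  Returns the grid point with the highest mean
#' AUC (ties broken towards the smallest n); folds with fewer extracted
#' features contribute no vote beyond their feature count.
#'
#' @param train Training `ExpressionDataset` (>= 5 samples per class).
#' @param method Extractor name, see [extract_features()].
#' @param secondary Secondary source for the extractor.
#' @param clf_kind Classifier kind, see [train_classifier()].
#' @param grid Candidate feature counts (default `1..min(max available,
#'   400)`).
#' @param params Extractor parameters.
#' @param n_folds Number of folds.
#' @return List with `n` (selected count), `mean_auc` at that count, and the
#'   full `curve` data frame (`n`, `mean_auc`, `votes`).
#' @export
cv_select_n <- function(train, method, secondary = NULL, clf_kind = "nmc",
                        grid = NULL, params = NULL, n_folds = 5L) {
  if (min(sum(train$labels == 1L), sum(train$labels == 0L)) < n_folds)
    stopf("need at least %d samples per class for stratified folds", n_folds)
  seed <- seed_from_fingerprint(canonical_fingerprint(train, "cv-folds"))
  fold <- stratified_folds(train, n_folds, seed)
  auc_by_n <- list()
  for (f in seq_len(n_folds)) {
    tr <- subset_samples(train, fold != f)
    va <- subset_samples(train, fold == f)
    feats <- extract_features(tr, method, secondary, params)
    if (!length(feats$features)) next
    blocks <- feature_col_blocks(tr, feats)
    fm_tr_full <- feature_matrix(tr, feats)
    fm_va_full <- feature_matrix(va, feats)
    ns <- if (is.null(grid)) seq_len(min(length(feats), 400L))
          else grid[grid <= length(feats)]
    for (n in ns) {
      cols <- unlist(blocks[seq_len(n)], use.names = FALSE)
      clf <- train_classifier(subset_feature_matrix(fm_tr_full, cols),
                              clf_kind)
      sc <- classifier_score(clf, subset_feature_matrix(fm_va_full, cols))
      auc_by_n[[as.character(n)]] <- c(auc_by_n[[as.character(n)]],
                                       auc(sc, va$labels))
    }
  }
  if (!length(auc_by_n)) stopf("no features extracted in any fold")
  ns <- sort(as.integer(names(auc_by_n)))
  curve <- data.frame(n = ns,
                      mean_auc = vapply(as.character(ns), function(n)
                        mean(auc_by_n[[n]]), numeric(1L)),
                      votes = vapply(as.character(ns), function(n)
                        length(auc_by_n[[n]]), integer(1L)))
  best <- curve$n[[which.max(curve$mean_auc)]]  # first max = smallest n
  list(n = best, mean_auc = max(curve$mean_auc), curve = curve)
}

policy_fixed_n <- function(policy) {
  if (startsWith(policy, "fixed_"))
    as.integer(sub("fixed_", "", policy)) else NA_integer_
}

eval_record <- function(method, secondary, clf_kind, train_name, test_name,
                        policy, n_used = NA_integer_, auc = NA_real_,
                        feasible = TRUE, converged = TRUE) {
  data.frame(method = method,
             secondary_source = if (is.null(secondary)) "none"
                                else secondary$name,
             classifier_kind = clf_kind, train_name = train_name,
             test_name = test_name, n_features_policy = policy,
             n_features_used = n_used, auc = auc, feasible = feasible,
             converged = converged, stringsAsFactors = FALSE)
}

#' Train on one cohort, test on an independent cohort
#'
#' Determines the number of features according to `policy` (`"cv_opt"` runs
#' [cv_select_n()]; `"fixed_<k>"` uses k and records infeasibility when
#' fewer than k features are extracted), re-extracts features on the full
#' training set, trains the classifier on the full training set and computes
#' the AUC once on the untouched test set.
#'
#' @param train,test `ExpressionDataset`s with `train$name != test$name`.
#' @param method,secondary,clf_kind,params,grid See [cv_select_n()].
#' @param policy `"cv_opt"` or `"fixed_<k>"` (e.g. `"fixed_50"`).
#' @return A one-row `EvalRecord` data frame.
#' @export
train_and_test <- function(train, test, method, secondary = NULL,
                           clf_kind = "nmc", policy = "cv_opt",
                           params = NULL, grid = NULL) {
  if (identical(train$name, test$name))
    stopf("training and test set must differ ('%s')", train$name)
  feats <- extract_features(train, method, secondary, params)
  n_avail <- length(feats)
  fixed <- policy_fixed_n(policy)
  if (!is.na(fixed)) {
    if (n_avail < fixed) {
      message(sprintf("%s/%s: only %d features, %s infeasible",
                      method, train$name, n_avail, policy))
      return(eval_record(method, secondary, clf_kind, train$name, test$name,
                         policy, feasible = FALSE))
    }
    n_star <- fixed
  } else if (policy == "cv_opt") {
    sel <- cv_select_n(train, method, secondary, clf_kind, grid, params)
    n_star <- min(sel$n, n_avail)
    if (n_avail == 0L)
      return(eval_record(method, secondary, clf_kind, train$name, test$name,
                         policy, feasible = FALSE))
  } else stopf("unknown policy '%s'", policy)
  fm_train <- feature_matrix(train, feats, n_star)
  clf <- train_classifier(fm_train, clf_kind)
  fm_test <- feature_matrix(test, feats, n_star)
  sc <- classifier_score(clf, fm_test)
  converged <- clf$converged %||% TRUE
  if (!converged)
    message(sprintf("%s/%s->%s: classifier did not converge; flagged",
                    method, train$name, test$name))
  eval_record(method, secondary, clf_kind, train$name, test$name, policy,
              n_star, auc(sc, test$labels), converged = converged)
}

#' Paired cross-dataset evaluation
#'
#' Runs [train_and_test()] for every ordered pair of distinct cohorts; D
#' cohorts yield `D * (D - 1)` records.
#'
#' @param datasets List of `ExpressionDataset`s.
#' @param ... Passed to [train_and_test()].
#' @return An `EvalRecord` data frame.
#' @export
paired_setting <- function(datasets, ...) {
  records <- list()
  for (i in seq_along(datasets)) for (j in seq_along(datasets)) {
    if (i == j) next
    records[[length(records) + 1L]] <-
      train_and_test(datasets[[i]], datasets[[j]], ...)
  }
  if (!length(records))
    return(eval_record("none", NULL, "none", "a", "b", "cv_opt")[0L, ])
  do.call(rbind, records)
}

#' Merged (leave-one-cohort-out) evaluation
#'
#' For each cohort, the remaining cohorts are pooled with [merge_datasets()]
#' (row concatenation followed by z-normalization) to form the training set;
#' D cohorts yield D records.
#'
#' @param datasets List of `ExpressionDataset`s (>= 2).
#' @param ... Passed to [train_and_test()].
#' @return An `EvalRecord` data frame.
#' @export
merged_setting <- function(datasets, ...) {
  stopifnot(length(datasets) >= 2L)
  do.call(rbind, lapply(seq_along(datasets), function(i) {
    train <- merge_datasets(datasets[-i],
                            name = paste0("merged_wo_",
                                          datasets[[i]]$name))
    train_and_test(train, datasets[[i]], ...)
  }))
}

#' ER-stratified merged evaluation
#'
#' Filters every cohort to its ER-positive cases *before* pooling and
#' normalization, then runs the merged setting: the test set is the
#' ER-positive part of one cohort, the training set pools the ER-positive
#' cases of all others.  Cohorts whose ER-positive part cannot be evaluated
#' (missing class) produce an infeasibility record.
#'
#' @param datasets List of `ExpressionDataset`s carrying `er_status`.
#' @param method,secondary,clf_kind Passed to [train_and_test()].
#' @param ... Further arguments for [train_and_test()].
#' @return An `EvalRecord` data frame with one row per cohort.
#' @export
er_stratified_setting <- function(datasets, method, secondary = NULL,
                                  clf_kind = "nmc", ...) {
  er_part <- lapply(datasets, function(ds) {
    if (is.null(ds$er_status)) stopf("'%s' has no er_status", ds$name)
    if (!any(ds$er_status == 1L)) return(NULL)
    subset_samples(ds, ds$er_status == 1L)
  })
  do.call(rbind, lapply(seq_along(datasets), function(i) {
    test <- er_part[[i]]
    rest <- er_part[-i]
    rest <- rest[!vapply(rest, is.null, logical(1L))]
    if (is.null(test) || length(unique(test$labels)) < 2L ||
        !length(rest)) {
      message(sprintf("'%s': ER-positive subset not evaluable",
                      datasets[[i]]$name))
      return(eval_record(method, secondary, clf_kind,
                         paste0("merged_er_wo_", datasets[[i]]$name),
                         datasets[[i]]$name, "er", feasible = FALSE))
    }
    train <- merge_datasets(rest, name = paste0("merged_er_wo_",
                                                datasets[[i]]$name))
    train_and_test(train, test, method, secondary, clf_kind, ...)
  }))
}

#' Win/loss comparison matrix
#'
#' For every pair of method/source combinations, counts over the shared
#' (train, test) pairs how often combination i's AUC beats combination j's
#' on the same test data; entry (i, j) is `log2((wins + 1) / (losses + 1))`
#' (draws count for neither side), giving an antisymmetric matrix with zero
#' diagonal.
#'
#' @param records An `EvalRecord` data frame covering several combinations.
#' @return A square numeric matrix with combination labels.
#' @export
win_loss <- function(records) {
  records <- records[records$feasible & records$converged, , drop = FALSE]
  combo <- paste(records$method, records$secondary_source, sep = "/")
  combos <- sort(unique(combo))
  m <- matrix(0, length(combos), length(combos),
              dimnames = list(combos, combos))
  key <- paste(records$train_name, records$test_name)
  for (i in seq_along(combos)) for (j in seq_along(combos)) {
    if (i >= j) next
    a <- records[combo == combos[[i]], ]
    b <- records[combo == combos[[j]], ]
    shared <- intersect(paste(a$train_name, a$test_name),
                        paste(b$train_name, b$test_name))
    if (!length(shared)) next
    aa <- a$auc[match(shared, paste(a$train_name, a$test_name))]
    bb <- b$auc[match(shared, paste(b$train_name, b$test_name))]
    wins <- sum(aa > bb); losses <- sum(aa < bb)
    m[i, j] <- log2((wins + 1) / (losses + 1))
    m[j, i] <- -m[i, j]
  }
  m
}

#' Paired Wilcoxon comparison of two matched AUC series
#'
#' Signed-rank test over matched (train, test) pairs: exact null for up to
#' 25 non-zero differences, normal approximation with continuity correction
#' otherwise; zero differences are dropped (if all differences are zero the
#' p-value is 1).  The Bonferroni-adjusted p multiplies by
#' `n_comparisons`.
#'
#' @param records_a,records_b `EvalRecord` data frames (matched on
#'   train/test names) or plain numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"` (a tends to beat b) or
#'   `"less"`.
#' @param n_comparisons Size of the comparison family for Bonferroni.
#' @return List with `p_value`, `p_adjusted`, `n_pairs`.
#' @export
compare_methods <- function(records_a, records_b,
                            alternative = c("two.sided", "greater", "less"),
                            n_comparisons = 1L) {
  alternative <- match.arg(alternative)
  if (is.data.frame(records_a)) {
    key_a <- paste(records_a$train_name, records_a$test_name)
    key_b <- paste(records_b$train_name, records_b$test_name)
    shared <- intersect(key_a, key_b)
    x <- records_a$auc[match(shared, key_a)]
    y <- records_b$auc[match(shared, key_b)]
  } else {
    x <- as.numeric(records_a); y <- as.numeric(records_b)
    if (length(x) != length(y)) stopf("unmatched series")
  }
  d <- x - y
  d <- d[!is.na(d)]
  nz <- sum(d != 0)
  p <- if (nz == 0L) 1 else suppressWarnings(
    stats::wilcox.test(d[d != 0], alternative = alternative,
                       exact = nz <= 25L, correct = TRUE)$p.value)
  list(p_value = p, p_adjusted = min(1, p * n_comparisons), n_pairs = nz)
}
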
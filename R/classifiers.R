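# Classifiers over feature matrices: nearest-mean (NMC), weighted 3-nearest
# neighbour (3NN), and logistic regression with a small ridge guard; plus the
# Mann-Whitney AUC.  Higher scores always mean "more poor-like".

check_provenance <- function(clf, fm) {
  if (!identical(clf$provenance, fm$provenance))
    stopf("feature-matrix columns do not match the training provenance")
}

#' Train a classifier on a feature matrix
#'
#' @param fm A `FeatureMatrix` (see [feature_matrix()]).
#' @param kind `"nmc"`, `"knn3"` or `"logistic"`.
#' @param ... Passed to the specific trainer (e.g. `lambda` for logistic).
#' @return A `TrainedClassifier`.
#' @export
train_classifier <- function(fm, kind = c("nmc", "knn3", "logistic"), ...) {
  kind <- match.arg(kind)
  switch(kind, nmc = train_nmc(fm), knn3 = train_knn3(fm),
         logistic = train_logistic(fm, ...))
}

#' Score samples with a trained classifier
#'
#' @param clf A `TrainedClassifier`.
#' @param fm A `FeatureMatrix` with the same column provenance as the
#'   training matrix.
#' @return Numeric score per sample; higher = more poor-like.
#' @export
classifier_score <- function(clf, fm) {
  check_provenance(clf, fm)
  switch(clf$kind,
         nmc = nmc_score(clf, fm),
         knn3 = knn_score(clf, fm),
         logistic = logistic_score(clf, fm))
}

#' Nearest-mean classifier
#'
#' Each sample is projected on the line connecting the two class means; the
#' score is the Euclidean distance of the projection to the good-class mean
#' minus its distance to the poor-class mean, so positive scores are
#' poor-like.  A score of exactly 0 (the midpoint) is classified good.
#'
#' @param fm A `FeatureMatrix` with both classes present.
#' @return A `TrainedClassifier` of kind `nmc`.
#' @export
train_nmc <- function(fm) {
  p <- fm$labels == 1L
  if (!any(p) || all(p)) stopf("both classes needed to train the NMC")
  structure(list(kind = "nmc",
                 mean_good = colMeans(fm$values[!p, , drop = FALSE]),
                 mean_poor = colMeans(fm$values[p, , drop = FALSE]),
                 provenance = fm$provenance),
            class = "TrainedClassifier")
}

#' @rdname train_nmc
#' @param clf A trained NMC.
#' @export
nmc_score <- function(clf, fm) {
  check_provenance(clf, fm)
  d <- clf$mean_poor - clf$mean_good
  dd <- sum(d^2)
  if (dd == 0) return(stats::setNames(rep(0, nrow(fm$values)),
                                      rownames(fm$values)))
  t <- as.numeric(sweep(fm$values, 2L, clf$mean_good) %*% d) / dd
  # projection = mean_good + t * d; distances along the line are |t|*||d||
  # and |t-1|*||d||
  sqrt(dd) * (abs(t) - abs(t - 1))
}

#' Weighted 3-nearest-neighbour classifier
#'
#' A query sample is scored by the label-weighted vote of its 3 nearest
#' training samples (Euclidean distance), each neighbour weighted by its
#' normalized inverse distance.  A zero-distance neighbour takes all the
#' weight (split equally if several are at distance zero).
#'
#' @param fm Training `FeatureMatrix`.
#' @return A `TrainedClassifier` of kind `knn3`.
#' @export
train_knn3 <- function(fm) {
  structure(list(kind = "knn3", train_values = fm$values,
                 train_labels = fm$labels, k = 3L,
                 provenance = fm$provenance),
            class = "TrainedClassifier")
}

#' @rdname train_knn3
#' @param clf A trained 3NN classifier.
#' @export
knn_score <- function(clf, fm) {
  check_provenance(clf, fm)
  k <- min(clf$k, nrow(clf$train_values))
  apply(fm$values, 1L, function(x) {
    d <- sqrt(colSums((t(clf$train_values) - x)^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    w <- if (any(dn == 0)) {
      z <- as.numeric(dn == 0)
      z / sum(z)
    } else {
      inv <- 1 / dn
      inv / sum(inv)
    }
    sum(w * clf$train_labels[nn])
  })
}

#' Logistic regression with ridge guard
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares, with an optional L2 penalty on the non-intercept weights
#' (default `lambda = 1e-4`).  Without the penalty the fit reproduces the
#' known pathology on wide matrices: the optimizer fails to converge and the
#' classifier is flagged (`converged = FALSE`) so evaluation summaries can
#' exclude it.
#'
#' @param fm Training `FeatureMatrix`.
#' @param lambda Ridge penalty (0 = plain maximum likelihood).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficient change.
#' @return A `TrainedClassifier` of kind `logistic` with a `converged` flag.
#' @export
train_logistic <- function(fm, lambda = 1e-4, max_iter = 100L, tol = 1e-8) {
  x <- cbind(`(Intercept)` = 1, fm$values)
  y <- fm$labels
  p <- ncol(x)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(x, y - mu) - pen %*% beta
    hess <- crossprod(x * w, x) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + as.numeric(step)
    if (any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol || max(abs(beta)) > 1e8) {
      converged <- delta < tol && max(abs(beta)) <= 1e8
      break
    }
  }
  if (!converged)
    message("logistic regression did not converge; classifier flagged")
  structure(list(kind = "logistic", beta = as.numeric(beta),
                 converged = converged, lambda = lambda,
                 provenance = fm$provenance),
            class = "TrainedClassifier")
}

#' @rdname train_logistic
#' @param clf A trained logistic classifier.
#' @export
logistic_score <- function(clf, fm) {
  check_provenance(clf, fm)
  as.numeric(cbind(1, fm$values) %*% clf$beta)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a poor-outcome sample outscores a good-outcome sample,
#' counting ties as 1/2, averaged over all poor/good pairs.
#'
#' @param scores Numeric scores (higher = more poor-like).
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes needed to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
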
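#' Fit / apply training-set standardization
#'
#' `standardize_fit()` learns per-feature mean and sample SD (n - 1
#' divisor) from the training subjects; `standardize_apply()` converts any
#' feature matrix to z-scores using those training parameters only, so held
#' out subjects never influence the scaling. Features with zero training SD
#' carry no information for that fold and are flagged for dropping.
#'
#' @param X numeric matrix or data.frame, subjects x features.
#' @return `standardize_fit()`: a list with `mean`, `sd` and `keep` (logical,
#'   SD > 0); `standardize_apply()`: the z-scored matrix restricted to kept
#'   features.
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0L) stop("empty training set")
  m <- colMeans(X)
  s <- if (n > 1L)
    sqrt(colSums((X - rep(m, each = n))^2) / (n - 1))
  else rep(0, ncol(X))
  names(s) <- colnames(X)
  list(mean = m, sd = s, keep = s > 0)
}

#' @rdname standardize_fit
#' @param params parameters from `standardize_fit()`.
#' @export
standardize_apply <- function(X, params) {
  X <- as.matrix(X)[, params$keep, drop = FALSE]
  m <- params$mean[params$keep]
  s <- params$sd[params$keep]
  sweep(sweep(X, 2, m), 2, s, "/")
}

# ridge-penalized logistic IRLS; lambda = 0 is plain MLE. Intercept is never
# penalized. Used as the fallback when the unpenalized fit separates.
ridge_logistic_irls <- function(X, y, lambda = 0, tol = 1e-8, max_iter = 100L) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * w, Xd) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit a logistic regression for diagnosis prediction
#'
#' Unregularized maximum-likelihood logistic regression (via
#' [stats::glm.fit()]) of a binary diagnosis on standardized features. If
#' the fit shows complete or quasi-complete separation (fitted
#' probabilities pinned at 0/1, or non-convergence), the model is refit
#' with a small ridge penalty so coefficients stay finite; the result is
#' flagged.
#'
#' @param X numeric matrix of standardized features (subjects x features).
#' @param y binary labels (0/1).
#' @param ridge_lambda penalty used only by the separation fallback.
#' @return a `logistic_model` list: `intercept`, `coef` (named), `separable`
#'   (logical flag).
#' @export
fit_logistic <- function(X, y, ridge_lambda = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  Xd <- cbind(`(Intercept)` = 1, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  # rank deficiency (collinear features) yields NA coefficients; treat it
  # like separation and let the ridge make the problem well posed
  if (!fit$converged || any(!is.finite(fit$coefficients)) ||
      any(mu < 1e-8 | mu > 1 - 1e-8)) separated <- TRUE
  if (separated) {
    beta <- ridge_logistic_irls(X, y, lambda = ridge_lambda)
  } else {
    beta <- fit$coefficients
  }
  cf <- beta[-1L]
  names(cf) <- colnames(X)
  structure(list(intercept = unname(beta[1L]), coef = cf,
                 separable = separated),
            class = "logistic_model")
}

#' @rdname fit_logistic
#' @param model a fitted `logistic_model`.
#' @param x feature matrix (or vector for one subject) on the same
#'   standardized scale as the training data.
#' @return predicted probabilities in (0, 1).
#' @export
predict_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  eta <- model$intercept + drop(as.matrix(x) %*% model$coef)
  stats::plogis(eta)
}

#' Confusion-matrix classification metrics at a score threshold
#'
#' Predictions are positive when `score >= tau`. Sensitivity is
#' TP / (TP + FN) and specificity TN / (TN + FP); if a class is absent the
#' corresponding rate is reported as 0 and flagged undefined.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels aligned with `scores`.
#' @param tau decision threshold.
#' @return list with `confusion` (TP, FP, TN, FN), `accuracy`,
#'   `sensitivity`, `specificity`, `error_rate`, `n` and definedness flags.
#' @export
classification_metrics <- function(scores, labels, tau = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  npos <- tp + fn
  nneg <- tn + fp
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = (tp + tn) / n,
       sensitivity = if (npos > 0) tp / npos else 0,
       specificity = if (nneg > 0) tn / nneg else 0,
       sensitivity_defined = npos > 0,
       specificity_defined = nneg > 0,
       error_rate = (fp + fn) / n,
       n = n)
}

#' Empirical ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (plus one above the maximum)
#' and records false- and true-positive rates; the AUC is the trapezoidal
#' area, which for the empirical ROC equals the rank-sum concordance
#' statistic with half credit for ties.
#'
#' @inheritParams classification_metrics
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Leave-one-subject-out cross-validated classification
#'
#' Each subject is held out once; on the remaining subjects the feature
#' table is z-scored ([standardize_fit()]), the `k` most separable features
#' are chosen by Davies-Bouldin score ([select_top_features()]) and a
#' logistic regression is fit ([fit_logistic()]). The held-out subject is
#' standardized with the training parameters, reduced to the same features
#' and scored. Standardization and selection are refit inside every fold,
#' so no information from the held-out subject leaks into the model that
#' predicts it.
#'
#' @param table feature table: numeric matrix/data.frame, subjects x named
#'   features.
#' @param labels binary diagnosis labels, one per subject.
#' @param k number of features selected per fold.
#' @param tau decision threshold for the hard prediction.
#' @param scatter Davies-Bouldin scatter variant, see [db_index()].
#' @param ridge_lambda separation-fallback penalty, see [fit_logistic()].
#' @return a `cv_result` list: `scores` (one out-of-fold probability per
#'   subject), `predicted`, `labels`, metrics (as in
#'   [classification_metrics()]), `roc`, `auc`, `fold_selected` (list of
#'   per-fold selected feature names), `selection_counts` (times each
#'   feature was selected across folds), `tau`, `k`.
#' @export
loso_evaluate <- function(table, labels, k = 10L, tau = 0.5,
                          scatter = "mad", ridge_lambda = 1e-4) {
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(as.logical(labels))
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(y) != n) stop("labels must match the number of subjects")
  if (length(unique(y)) < 2L) stop("both classes must be present")

  scores <- numeric(n)
  fold_selected <- vector("list", n)
  # leave-one-out updates of per-fold training mean/SD (z-scoring is
  # label-free, so only the held-out row changes fold to fold); feature
  # ranking runs on the raw training columns because the Davies-Bouldin
  # score is invariant under the per-feature affine map that z-scoring
  # applies, and only the k selected columns are then standardized
  csum <- colSums(X)
  csum2 <- colSums(X^2)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop("fold ", i, ": training labels are single-class; cannot fit")
    mu <- (csum - X[i, ]) / (n - 1)
    ss <- pmax((csum2 - X[i, ]^2) - (n - 1) * mu^2, 0)
    sdev <- sqrt(ss / (n - 2))
    keep <- sdev > 1e-10 * (1 + abs(mu))  # drop fold-constant features
    Xtr <- X[-i, keep, drop = FALSE]
    sel <- select_top_features(Xtr, ytr, k = min(k, ncol(Xtr)),
                               scatter = scatter)
    feats <- sel$selected
    mu_f <- mu[feats]; sd_f <- sdev[feats]
    Ztr <- sweep(sweep(Xtr[, feats, drop = FALSE], 2, mu_f), 2, sd_f, "/")
    model <- fit_logistic(Ztr, ytr, ridge_lambda = ridge_lambda)
    zte <- (X[i, feats] - mu_f) / sd_f
    scores[i] <- predict_score(model, zte)
    fold_selected[[i]] <- feats
  }

  met <- classification_metrics(scores, y, tau = tau)
  roc <- roc_auc(scores, y)
  counts <- table(factor(unlist(fold_selected), levels = colnames(X)))
  structure(c(list(scores = scores, predicted = as.integer(scores >= tau),
                   labels = y, fold_selected = fold_selected,
                   selection_counts = counts, roc = roc$roc, auc = roc$auc,
                   tau = tau, k = k),
              met),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> n = %d folds | accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f (tau = %g)\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$auc, x$tau))
  invisible(x)
}
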
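# Standardization, logistic fitting, metrics, ROC/AUC and the LOSO loop

test_that("standardization learns train parameters and applies them", {
  p <- standardize_fit(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(unname(standardize_apply(matrix(c(1, 2, 3)), p)[, 1]),
               c(-1, 0, 1))
  expect_equal(unname(standardize_apply(matrix(2), p)[, 1]), 0)
  # idempotence: refitting on standardized training data recovers (0, 1)
  X <- matrix(rnorm(60), 20, 3)
  pz <- standardize_fit(X)
  Z <- standardize_apply(X, pz)
  pz2 <- standardize_fit(Z)
  expect_equal(unname(pz2$mean), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(pz2$sd), rep(1, 3), tolerance = 1e-12)
  # zero-SD features flagged for dropping
  pc <- standardize_fit(cbind(rnorm(10), rep(4, 10)))
  expect_identical(unname(pc$keep), c(TRUE, FALSE))
  expect_error(standardize_fit(matrix(numeric(0), 0, 2)), "empty")
})

test_that("logistic fit recovers the intercept-only MLE on null features", {
  set.seed(8)
  X <- matrix(rnorm(400), 100, 4)
  y <- rep(c(1, 0), c(30, 70))
  m <- fit_logistic(X, y)
  expect_false(m$separable)
  expect_equal(m$intercept, qlogis(0.3), tolerance = 0.25)
  expect_equal(unname(m$coef), rep(0, 4), tolerance = 0.3)
  # score at eta = 0 is exactly 0.5
  m0 <- list(intercept = 0, coef = c(f = 0))
  expect_equal(unname(predict_score(m0, matrix(5))), 0.5)
})

test_that("complete separation engages the ridge fallback", {
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- expect_silent(fit_logistic(X, y))
  expect_true(m$separable)
  expect_true(all(is.finite(c(m$intercept, m$coef))))
  sc <- predict_score(m, X)
  expect_true(all(sc[y == 1] > 0.5) && all(sc[y == 0] < 0.5))
})

test_that("collinear features fall back to a well-posed ridge fit", {
  set.seed(9)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x - 1, c = rnorm(30))  # a and b aliased
  y <- rbinom(30, 1, plogis(x))
  y[1] <- 1L; y[2] <- 0L
  m <- fit_logistic(X, y)
  expect_true(all(is.finite(c(m$intercept, m$coef))))
  expect_true(all(is.finite(predict_score(m, X))))
})

test_that("metrics reproduce the unique 21/41 confusion table", {
  # TP=14, FN=7, TN=36, FP=5 on 21 cases / 41 controls
  scores <- c(rep(1, 14), rep(0, 7), rep(0, 36), rep(1, 5))
  labels <- c(rep(1, 21), rep(0, 41))
  met <- classification_metrics(scores, labels, tau = 0.5)
  expect_equal(unname(met$confusion), c(14, 5, 36, 7))
  expect_equal(met$accuracy, 50 / 62)
  expect_equal(met$sensitivity, 14 / 21)
  expect_equal(met$specificity, 36 / 41)
  expect_equal(round(met$accuracy, 2), 0.81)
  expect_equal(round(met$sensitivity, 2), 0.67)
  expect_equal(round(met$specificity, 2), 0.88)
})

test_that("metric edge cases follow the documented conventions", {
  met <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(met$accuracy, met$sensitivity, met$specificity), c(1, 1, 1))
  # all predicted negative
  met2 <- classification_metrics(rep(0, 4), c(1, 1, 0, 0), tau = 0.5)
  expect_equal(met2$sensitivity, 0)
  expect_equal(met2$specificity, 1)
  # no positive labels at all: sensitivity reported 0 and flagged
  met3 <- classification_metrics(c(0.2, 0.7), c(0, 0))
  expect_equal(met3$sensitivity, 0)
  expect_false(met3$sensitivity_defined)
  # boundary: score equal to tau predicts positive
  met4 <- classification_metrics(0.5, 1, tau = 0.5)
  expect_equal(unname(met4$confusion["TP"]), 1L)
})

test_that("ROC/AUC matches closed forms and the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(0, 1), 3))$auc, 0.5)
  expect_equal(roc_auc(c(.1, .4, .35, .8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(10)
  for (trial in 1:1000) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 0), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.35)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qlogis(scores), labels)$auc, base)
  expect_equal(roc_auc(scores^3, labels)$auc, base)
  expect_equal(roc_auc(rank(scores), labels)$auc, base)
})

test_that("threshold monotonicity of sensitivity and specificity", {
  set.seed(13)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.4)
  taus <- seq(0, 1, by = 0.1)
  sens <- vapply(taus, function(t)
    classification_metrics(scores, labels, t)$sensitivity, numeric(1))
  spec <- vapply(taus, function(t)
    classification_metrics(scores, labels, t)$specificity, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("LOSO produces one out-of-fold score per subject", {
  s <- planted_table(gap = 0, seed = 21)
  # make the planted feature genuinely separable: 5-SD gap with tight
  # within-class scatter
  s$table[, "f1"] <- 5 * s$labels + 0.5 * s$table[, "f1"]
  stopifnot(min(s$table[s$labels == 1, "f1"]) >
              max(s$table[s$labels == 0, "f1"]))
  cv <- loso_evaluate(s$table, s$labels, k = 5)
  expect_length(cv$scores, 20L)
  expect_length(cv$fold_selected, 20L)
  expect_equal(sum(cv$confusion), cv$n)
  # a 5-SD gap is essentially perfectly separable
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auc, 1)
})

test_that("LOSO matches a naive per-fold reference implementation", {
  s <- planted_table(n_case = 6, n_control = 8, p = 12, gap = 2, seed = 31)
  cv <- loso_evaluate(s$table, s$labels, k = 4)
  n <- nrow(s$table)
  for (i in c(1, 5, n)) {
    Xtr <- s$table[-i, , drop = FALSE]
    ytr <- s$labels[-i]
    pz <- standardize_fit(Xtr)
    Ztr <- standardize_apply(Xtr, pz)
    sel <- select_top_features(Ztr, ytr, k = 4)
    expect_identical(cv$fold_selected[[i]], sel$selected)
    model <- fit_logistic(Ztr[, sel$selected, drop = FALSE], ytr)
    zte <- standardize_apply(s$table[i, , drop = FALSE],
                             pz)[, sel$selected, drop = FALSE]
    expect_equal(cv$scores[i], unname(predict_score(model, zte)),
                 tolerance = 1e-8)
  }
})

test_that("no leakage: corrupting the held-out subject changes nothing", {
  s <- planted_table(n_case = 6, n_control = 8, p = 12, gap = 2, seed = 32)
  cv <- loso_evaluate(s$table, s$labels, k = 4)
  for (i in c(2, 9)) {
    X2 <- s$table
    X2[i, ] <- 1e3 * rnorm(ncol(X2))   # corrupt the held-out row
    Xtr <- X2[-i, , drop = FALSE]
    pz <- standardize_fit(Xtr)
    Ztr <- standardize_apply(Xtr, pz)
    sel <- select_top_features(Ztr, s$labels[-i], k = 4)
    # fold i's selection and model are untouched by subject i's values
    expect_identical(sel$selected, cv$fold_selected[[i]])
    model <- fit_logistic(Ztr[, sel$selected, drop = FALSE], s$labels[-i])
    cv2 <- loso_evaluate(X2, s$labels, k = 4)
    expect_identical(cv2$fold_selected[[i]], cv$fold_selected[[i]])
    zi <- standardize_apply(s$table[i, , drop = FALSE],
                            pz)[, sel$selected, drop = FALSE]
    expect_equal(cv2$scores[-i] == cv$scores[-i],
                 rep(FALSE, length(cv$scores) - 1)) # other folds do change
    expect_equal(unname(predict_score(model, zi)), cv$scores[i],
                 tolerance = 1e-8)
  }
})

test_that("null features give chance-level accuracy within the binomial band", {
  accs <- vapply(1:10, function(r) {
    s <- simulate_feature_table(8, 12, feature_names_ = paste0("f", 1:20),
                                seed = 700 + r)
    loso_evaluate(s$table, s$labels, k = 5)$accuracy
  }, numeric(1))
  # base rate 0.6; LOSO on noise is typically at or below it
  expect_true(mean(accs) > 0.25 && mean(accs) < 0.75)
})

test_that("LOSO input validation", {
  s <- planted_table(seed = 40)
  expect_error(loso_evaluate(s$table[1:2, ], s$labels[1:2]), "at least 3")
  expect_error(loso_evaluate(s$table, rep(1, 20)), "both classes")
  # removing the only case in a fold must abort, not silently fit
  X <- matrix(rnorm(40), 10, 4)
  expect_error(loso_evaluate(X, c(1, rep(0, 9)), k = 2), "single-class")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.35)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<",
                                           levels = c(0, 1))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
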
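#' Two-class Davies-Bouldin separability score of one feature
#'
#' For a single feature split into two diagnostic groups the score is
#' `(S1 + S2) / |c1 - c2|`, where `c_i` is the class mean and `S_i` the
#' mean absolute deviation of class `i` about its mean (scatter exponent
#' q = 1; `scatter = "rms"` gives the q = 2 variant). Lower scores mean
#' better separated classes; coincident class centroids give `Inf`.
#'
#' @param values numeric feature values, one per subject.
#' @param labels binary labels (0/1 or logical), same length.
#' @param scatter `"mad"` (mean absolute deviation, default) or `"rms"`.
#' @return nonnegative scalar, possibly `Inf`.
#' @export
db_index <- function(values, labels, scatter = c("mad", "rms")) {
  scatter <- match.arg(scatter)
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  if (!all(c(0L, 1L) %in% labels)) stop("both classes must be present")
  x1 <- values[labels == 1L]
  x0 <- values[labels == 0L]
  c1 <- mean(x1); c0 <- mean(x0)
  s <- function(x, c) if (scatter == "mad") mean(abs(x - c)) else
    sqrt(mean((x - c)^2))
  d <- abs(c1 - c0)
  if (d == 0) return(Inf)
  (s(x1, c1) + s(x0, c0)) / d
}

# vectorized DB scores for every column of a feature matrix
db_scores <- function(X, labels, scatter = "mad") {
  labels <- as.logical(labels)
  X1 <- X[labels, , drop = FALSE]
  X0 <- X[!labels, , drop = FALSE]
  c1 <- colMeans(X1); c0 <- colMeans(X0)
  if (scatter == "mad") {
    s1 <- colMeans(abs(sweep(X1, 2, c1)))
    s0 <- colMeans(abs(sweep(X0, 2, c0)))
  } else {
    s1 <- sqrt(colMeans(sweep(X1, 2, c1)^2))
    s0 <- sqrt(colMeans(sweep(X0, 2, c0)^2))
  }
  d <- abs(c1 - c0)
  out <- ifelse(d == 0, Inf, (s1 + s0) / d)
  names(out) <- colnames(X)
  out
}

#' Rank features by Davies-Bouldin separability and keep the best k
#'
#' Scores every feature independently (univariate) with [db_index()] and
#' returns the `k` lowest-scoring ones. Ties are broken by original column
#' order (stable sort), so the ranking is a reproducible permutation of the
#' feature set. Zero-variance (constant) features have coincident class
#' centroids whenever both class means equal the constant, score `Inf`, and
#' therefore rank last.
#'
#' @param table numeric matrix or data.frame of features (subjects x
#'   features), standardized on the same subjects used for scoring.
#' @param labels binary diagnosis labels.
#' @param k number of features to keep.
#' @inheritParams db_index
#' @return a `selection_result` list: `ranking` (feature names, best
#'   first), `scores` (named DB scores in original column order),
#'   `selected` (the `k` chosen names).
#' @export
select_top_features <- function(table, labels, k = 10L,
                                scatter = c("mad", "rms")) {
  scatter <- match.arg(scatter)
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (k > ncol(X)) stop("k exceeds the number of features")
  scores <- db_scores(X, labels, scatter = scatter)
  ord <- order(scores, seq_along(scores))   # stable: ties keep column order
  ranking <- colnames(X)[ord]
  structure(list(ranking = ranking, scores = scores,
                 selected = ranking[seq_len(k)]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> top features:\n")
  print(utils::head(data.frame(feature = x$ranking,
                               db_score = unname(x$scores[x$ranking])),
                    length(x$selected)))
  invisible(x)
}
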
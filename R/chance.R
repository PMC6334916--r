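#' Sample plausible error rates from a beta distribution
#'
#' The uncertainty of an observed classification error rate (k incorrect
#' out of n) is approximated by a Beta(k + 1, n - k + 1) distribution --
#' the Bayes-Laplace posterior of the error probability, which stays proper
#' at k = 0 and k = n. The alternative Beta(k, n - k) shape is available
#' for comparison.
#'
#' @param n_incorrect number of incorrect predictions (k).
#' @param n_total total number of predictions (n).
#' @param m number of draws.
#' @param shape `"laplace"` for Beta(k + 1, n - k + 1) (default) or `"raw"`
#'   for Beta(k, n - k).
#' @return numeric vector of `m` error rates in `[0, 1]`.
#' @export
sample_error_beta <- function(n_incorrect, n_total, m = 100L,
                              shape = c("laplace", "raw")) {
  shape <- match.arg(shape)
  if (n_total <= 0 || n_incorrect < 0 || n_incorrect > n_total)
    stop("need 0 <= n_incorrect <= n_total and n_total > 0")
  if (shape == "laplace") {
    stats::rbeta(m, n_incorrect + 1, n_total - n_incorrect + 1)
  } else {
    if (n_incorrect == 0 || n_incorrect == n_total)
      stop("shape = 'raw' is degenerate at k = 0 or k = n")
    stats::rbeta(m, n_incorrect, n_total - n_incorrect)
  }
}

#' Null distribution of the error rate under label permutation
#'
#' Repeats the complete leakage-safe LOSO pipeline (fold-internal
#' standardization, Davies-Bouldin selection and logistic fit) on `m`
#' uniform random permutations of the diagnosis labels and records each
#' run's error rate. Permuting preserves class balance exactly; the
#' observed labeling is not forcibly excluded from the permutations.
#'
#' @inheritParams loso_evaluate
#' @param m number of label permutations.
#' @return numeric vector of `m` null error rates.
#' @export
permutation_null <- function(table, labels, m = 100L, k = 10L, tau = 0.5,
                             scatter = "mad", ridge_lambda = 1e-4) {
  y <- as.integer(as.logical(labels))
  vapply(seq_len(m), function(j) {
    yp <- sample(y)
    cv <- loso_evaluate(table, yp, k = k, tau = tau, scatter = scatter,
                        ridge_lambda = ridge_lambda)
    cv$error_rate
  }, numeric(1))
}

#' Compare observed and chance error-rate distributions
#'
#' Tests whether the classifier's plausible error rates differ from those
#' obtained by chance. The default pairs the two equal-length samples by
#' index and applies the two-sided Wilcoxon signed-rank test (the pairing
#' is arbitrary since both sides are i.i.d. draws); `paired = FALSE` uses
#' the unpaired two-sample Mann-Whitney U test instead. Direction is the
#' sign of the median difference.
#'
#' @param observed_samples error rates sampled around the observed
#'   performance, e.g. from [sample_error_beta()].
#' @param null_samples permutation error rates from [permutation_null()].
#' @param paired logical, see Details.
#' @return list with `p_value`, `direction` (`"below chance"`,
#'   `"above chance"` or `"no difference"`), `median_difference`, `method`.
#' @export
compare_to_chance <- function(observed_samples, null_samples, paired = TRUE) {
  if (length(observed_samples) == 0L || length(null_samples) == 0L)
    stop("empty sample vector")
  if (paired && length(observed_samples) != length(null_samples))
    stop("paired comparison needs equal-length samples")
  med_diff <- stats::median(observed_samples) - stats::median(null_samples)
  if (paired) {
    d <- observed_samples - null_samples
    if (all(d == 0)) {
      return(list(p_value = 1, direction = "no difference",
                  median_difference = 0, method = "wilcoxon signed-rank"))
    }
    ht <- suppressWarnings(stats::wilcox.test(observed_samples, null_samples,
                                              paired = TRUE, exact = FALSE))
    method <- "wilcoxon signed-rank"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(observed_samples, null_samples,
                                              paired = FALSE, exact = FALSE))
    method <- "mann-whitney U"
  }
  direction <- if (med_diff < 0) "below chance" else if (med_diff > 0)
    "above chance" else "no difference"
  list(p_value = ht$p.value, direction = direction,
       median_difference = med_diff, method = method)
}

#' Full chance test of a LOSO classifier
#'
#' Runs the LOSO pipeline on the observed labels, samples `m` plausible
#' error rates from the beta approximation around the observed error,
#' builds the permutation null ([permutation_null()]) and compares the two
#' distributions ([compare_to_chance()]).
#'
#' @inheritParams permutation_null
#' @inheritParams sample_error_beta
#' @inheritParams compare_to_chance
#' @return a `chance_test` list: `observed_error`, `observed_samples`,
#'   `null_samples`, `null_median`, `p_value`, `direction`, `m`.
#' @export
chance_test <- function(table, labels, m = 100L, k = 10L, tau = 0.5,
                        shape = "laplace", paired = TRUE, scatter = "mad",
                        ridge_lambda = 1e-4) {
  cv <- loso_evaluate(table, labels, k = k, tau = tau, scatter = scatter,
                      ridge_lambda = ridge_lambda)
  n_wrong <- as.integer(round(cv$error_rate * cv$n))
  obs <- sample_error_beta(n_wrong, cv$n, m = m, shape = shape)
  nul <- permutation_null(table, labels, m = m, k = k, tau = tau,
                          scatter = scatter, ridge_lambda = ridge_lambda)
  cmp <- compare_to_chance(obs, nul, paired = paired)
  structure(list(observed_error = cv$error_rate, observed_samples = obs,
                 null_samples = nul, null_median = stats::median(nul),
                 # percentile of the observed error within the permutation
                 # null: the classical one-sided permutation p-value, a
                 # useful diagnostic alongside the distribution comparison
                 null_percentile = mean(nul <= cv$error_rate),
                 p_value = cmp$p_value, direction = cmp$direction,
                 m = m, cv = cv),
            class = "chance_test")
}

#' @export
print.chance_test <- function(x, ...) {
  cat(sprintf(
    "<chance_test> observed error %.3f vs null median %.3f: p = %.4g (%s, m = %d)\n",
    x$observed_error, x$null_median, x$p_value, x$direction, x$m))
  invisible(x)
}
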
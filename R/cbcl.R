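# Questionnaire comparator: screening for internalizing diagnosis with
# Child Behavior Checklist (CBCL) T-score cutoffs and score-based AUC.

#' Classify subjects by a CBCL T-score cutoff
#'
#' A subject screens positive when the T score meets or exceeds the cutoff
#' (inclusive rule). The manualized clinical cutoff is T >= 70; T >= 55 is
#' a more conservative screening cutoff. Missing T scores yield `NA`
#' predictions; downstream metrics exclude those subjects listwise and
#' report the analyzed denominator.
#'
#' @param t_scores numeric T scores (typically in 20-100); may contain `NA`.
#' @param cutoff T-score cutoff (default 70).
#' @return integer vector of 0/1 predictions with `NA` where the score is
#'   missing.
#' @export
cutoff_classify <- function(t_scores, cutoff = 70) {
  if (all(is.na(t_scores))) stop("all T scores are missing")
  as.integer(t_scores >= cutoff)
}

#' Screening performance of a CBCL scale at a cutoff
#'
#' Applies [cutoff_classify()] and computes accuracy, sensitivity and
#' specificity against the clinical diagnosis via the shared metric
#' machinery. Subjects with a missing T score are excluded listwise; the
#' analyzed `n` and the number excluded are always reported because
#' questionnaire records are commonly incomplete.
#'
#' @param t_scores numeric T scores, one per subject (`NA` = missing).
#' @param diagnosis binary diagnosis labels aligned with `t_scores`.
#' @param cutoff T-score cutoff.
#' @return list as in [classification_metrics()] plus `n_excluded` and
#'   `cutoff`.
#' @export
cbcl_evaluate <- function(t_scores, diagnosis, cutoff = 70) {
  keep <- !is.na(t_scores)
  if (!any(keep)) stop("all T scores are missing")
  y <- as.integer(as.logical(diagnosis))[keep]
  if (length(unique(y)) < 2L)
    stop("single diagnostic class after missing-data exclusion")
  pred <- cutoff_classify(t_scores[keep], cutoff)
  met <- classification_metrics(as.numeric(pred), y, tau = 0.5)
  met$n_excluded <- sum(!keep)
  met$cutoff <- cutoff
  met
}

#' Threshold-free discrimination of a CBCL scale
#'
#' AUC of the continuous T score as a ranking statistic for the diagnosis
#' (cutoff-independent, invariant to monotone transforms of the scale).
#'
#' @inheritParams cbcl_evaluate
#' @return list with `auc`, `roc`, `n`, `n_excluded`.
#' @export
cbcl_auc <- function(t_scores, diagnosis) {
  keep <- !is.na(t_scores)
  y <- as.integer(as.logical(diagnosis))[keep]
  if (length(unique(y)) < 2L)
    stop("single diagnostic class after missing-data exclusion")
  r <- roc_auc(t_scores[keep], y)
  list(auc = r$auc, roc = r$roc, n = sum(keep), n_excluded = sum(!keep))
}

#' Simulate CBCL T scores for a labeled cohort
#'
#' Draws per-group normal T scores truncated to the plausible range
#' [20, 100] (redrawing out-of-range values), emulating a questionnaire
#' scale that is elevated on average in diagnosed children.
#'
#' @param labels binary diagnosis labels.
#' @param case_mean,case_sd T-score distribution of diagnosed subjects.
#' @param control_mean,control_sd T-score distribution of controls.
#' @return numeric vector of T scores aligned with `labels`.
#' @export
simulate_cbcl <- function(labels, case_mean = 62, case_sd = 8,
                          control_mean = 48, control_sd = 8) {
  y <- as.logical(labels)
  mu <- ifelse(y, case_mean, control_mean)
  sg <- ifelse(y, case_sd, control_sd)
  t <- stats::rnorm(length(y), mu, sg)
  bad <- t < 20 | t > 100
  while (any(bad)) {
    t[bad] <- stats::rnorm(sum(bad), mu[bad], sg[bad])
    bad <- t < 20 | t > 100
  }
  t
}
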
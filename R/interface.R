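# End-to-end experiment drivers used by the command-line interface
# (inst/cli/moodscreen.R) and the acceptance script.

#' Hash a run configuration
#'
#' Every output artifact embeds this hash together with the master seed so
#' a run can be reproduced exactly.
#'
#' @param config any JSON-serializable list.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

#' Run the full screening experiment on a feature table
#'
#' Mirrors the study's analysis end to end: per-phase leave-one-subject-out
#' logistic classification (accuracy / sensitivity / specificity / AUC),
#' the beta-sampled permutation chance test per phase, a feature-stability
#' report (how often each feature was selected across folds), and -- when
#' CBCL T scores are supplied -- the questionnaire cutoff comparator at
#' T >= 70 and T >= 55 plus score-based AUC.
#'
#' @param table a `feature_table` with rows for one or more phases.
#' @param phases phases to analyze.
#' @param cbcl optional data.frame with `diagnosis` plus any of
#'   `internalizing_t`, `anxiety_t`, `depressive_t` columns.
#' @param k features selected per fold.
#' @param tau decision threshold (0.375 is the screening-oriented
#'   secondary operating point).
#' @param m permutations / beta draws for the chance test; `0` skips it.
#' @param seed master seed for the chance test.
#' @param min_stable a feature counts as stable when selected in at least
#'   this fraction of folds.
#' @return a `screening_run` list with one entry per phase (`cv`,
#'   `chance`, `stable_features`) plus `cbcl`, `config` and `config_hash`.
#' @export
run_screening <- function(table, phases = phase_windows()$phase, cbcl = NULL,
                          k = 10L, tau = 0.5, m = 100L, seed = 1L,
                          min_stable = 58 / 62) {
  config <- list(phases = phases, k = k, tau = tau, m = m, seed = seed,
                 min_stable = min_stable)
  per_phase <- list()
  for (ph in phases) {
    fm <- feature_matrix(table, ph)
    cv <- loso_evaluate(fm$X, fm$labels, k = k, tau = tau)
    stable <- names(cv$selection_counts)[
      cv$selection_counts >= ceiling(min_stable * cv$n)]
    chance <- NULL
    if (m > 0L) {
      set.seed(seed)
      chance <- chance_test(fm$X, fm$labels, m = m, k = k, tau = tau)
    }
    per_phase[[ph]] <- list(cv = cv, chance = chance,
                            stable_features = stable)
  }
  cbcl_out <- NULL
  if (!is.null(cbcl)) {
    cbcl_out <- list()
    for (scale in intersect(c("internalizing_t", "anxiety_t", "depressive_t"),
                            names(cbcl))) {
      cbcl_out[[scale]] <- list(
        cutoff70 = cbcl_evaluate(cbcl[[scale]], cbcl$diagnosis, cutoff = 70),
        cutoff55 = cbcl_evaluate(cbcl[[scale]], cbcl$diagnosis, cutoff = 55),
        auc = cbcl_auc(cbcl[[scale]], cbcl$diagnosis)$auc)
    }
  }
  structure(list(phases = per_phase, cbcl = cbcl_out, config = config,
                 config_hash = config_hash(config), seed = seed),
            class = "screening_run")
}

#' @export
print.screening_run <- function(x, ...) {
  cat("<screening_run> config", substr(x$config_hash, 1, 8), "seed",
      x$seed, "\n")
  for (ph in names(x$phases)) {
    cv <- x$phases[[ph]]$cv
    line <- sprintf(
      "  %-18s acc %.3f sens %.3f spec %.3f AUC %.3f", ph, cv$accuracy,
      cv$sensitivity, cv$specificity, cv$auc)
    if (!is.null(x$phases[[ph]]$chance))
      line <- paste0(line, sprintf(" | chance p = %.3g (%s)",
                                   x$phases[[ph]]$chance$p_value,
                                   x$phases[[ph]]$chance$direction))
    cat(line, "\n")
  }
  if (!is.null(x$cbcl)) {
    for (scale in names(x$cbcl)) {
      s <- x$cbcl[[scale]]
      cat(sprintf(
        "  CBCL %-15s cutoff70 sens %.2f spec %.2f (n=%d) | cutoff55 sens %.2f spec %.2f | AUC %.3f\n",
        scale, s$cutoff70$sensitivity, s$cutoff70$specificity, s$cutoff70$n,
        s$cutoff55$sensitivity, s$cutoff55$specificity, s$auc))
    }
  }
  invisible(x)
}

#' Serialize a screening run to JSON
#'
#' @param run a `screening_run`.
#' @param path output JSON path.
#' @export
write_screening_json <- function(run, path) {
  phases <- lapply(run$phases, function(p) {
    out <- list(accuracy = p$cv$accuracy, sensitivity = p$cv$sensitivity,
                specificity = p$cv$specificity, auc = p$cv$auc,
                error_rate = p$cv$error_rate,
                stable_features = p$stable_features)
    if (!is.null(p$chance))
      out <- c(out, list(chance_p = p$chance$p_value,
                         chance_direction = p$chance$direction,
                         null_median = p$chance$null_median))
    out
  })
  jsonlite::write_json(
    list(config_hash = run$config_hash, seed = run$seed,
         config = run$config, phases = phases, cbcl = run$cbcl),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
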
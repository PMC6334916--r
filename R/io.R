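# Feature-table interchange: the CSV written here is the hub between the
# signal-processing half and the statistical half of the pipeline, so a
# supplementary per-subject table can substitute for raw recordings.

#' Write / read a per-subject feature table
#'
#' Layout: `subject_id`, `phase`, `diagnosis` (0/1), then one column per
#' named feature.
#'
#' @param table a `feature_table` data.frame (see [cohort_feature_table()]).
#' @param path CSV path.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv()`: a `feature_table` data.frame.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("subject_id", "phase", "diagnosis")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("feature CSV missing columns: ", paste(missing_cols, collapse = ", "))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Split a feature table into model inputs
#'
#' @param table a `feature_table`.
#' @param phase which phase's rows to use.
#' @return list with `X` (numeric matrix of features), `labels`,
#'   `subject_id`.
#' @export
feature_matrix <- function(table, phase = "PotentialThreat") {
  df <- as.data.frame(table)
  df <- df[df$phase == phase, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for phase ", phase)
  meta <- c("subject_id", "phase", "diagnosis")
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, labels = as.integer(df$diagnosis), subject_id = df$subject_id)
}

#' Read a supplementary subject table (XLSX or CSV)
#'
#' Reads a per-subject table in the layout of the study's supplementary
#' data file: per-phase feature columns, CBCL T scores and the clinical
#' diagnosis. Column mapping is configuration-driven because supplementary
#' layouts vary: `mapping` names the subject, diagnosis and (optionally)
#' CBCL columns; remaining numeric columns are treated as features.
#' Requires the `readxl` package for `.xlsx` input.
#'
#' @param path `.xlsx` or `.csv` file.
#' @param sheet sheet name or index (XLSX only).
#' @param mapping named list with entries `subject_id`, `diagnosis` and
#'   optionally `internalizing_t`, `anxiety_t`, `depressive_t`.
#' @return a data.frame with standardized metadata column names.
#' @export
read_subject_table <- function(path, sheet = 1,
                               mapping = list(subject_id = "subject_id",
                                              diagnosis = "diagnosis")) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  for (key in c("subject_id", "diagnosis", "internalizing_t", "anxiety_t",
                "depressive_t")) {
    src <- mapping[[key]]
    if (!is.null(src)) {
      if (!src %in% names(df))
        stop("mapped column '", src, "' (", key, ") not found in ", path)
      names(df)[names(df) == src] <- key
    }
  }
  if (!all(c("subject_id", "diagnosis") %in% names(df)))
    stop("subject table needs subject_id and diagnosis columns (via mapping)")
  df
}

#' Serialize a cross-validation result to JSON
#'
#' @param cv a `cv_result` from [loso_evaluate()].
#' @param path output JSON path.
#' @export
write_cv_json <- function(cv, path) {
  out <- list(n = cv$n, accuracy = cv$accuracy, sensitivity = cv$sensitivity,
              specificity = cv$specificity, auc = cv$auc,
              error_rate = cv$error_rate, tau = cv$tau, k = cv$k,
              confusion = as.list(cv$confusion), scores = cv$scores,
              labels = cv$labels,
              selection_counts = as.list(cv$selection_counts))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an ROC curve as CSV (threshold, FPR, TPR)
#'
#' @param roc the `roc` data.frame from [roc_auc()] or a `cv_result`.
#' @param path output CSV path.
#' @export
write_roc_csv <- function(roc, path) {
  if (inherits(roc, "cv_result")) roc <- roc$roc
  utils::write.csv(roc, path, row.names = FALSE)
  invisible(path)
}
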
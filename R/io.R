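# Delimited-text readers/writers and result serialization. The shell surface
# is a thin Rscript over these functions (inst/scripts/aiwrap).

#' Read a delimited table into a dataset
#'
#' Reads a CSV (or TSV, auto-detected from the `.tsv`/`.tab` extension) with
#' a header row, separates the outcome column, and validates that every
#' column is numeric and complete. Rows with missing values are rejected
#' with a count rather than silently dropped.
#'
#' @param path file path.
#' @param outcome outcome column name (default `"y"`).
#' @return an `aiwrap_dataset` (feature columns keep their file names).
#' @export
read_table <- function(path, outcome = "y") {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (nrow(df) == 0) stop("empty file: ", path)
  if (!outcome %in% names(df)) {
    stop("outcome column '", outcome, "' not found in ", path)
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric column(s): ", paste(non_num, collapse = ", "))
  }
  n_miss <- sum(!stats::complete.cases(df))
  if (n_miss > 0) stop(n_miss, " row(s) contain missing values; remove them first")
  y <- df[[outcome]]
  X <- as.matrix(df[setdiff(names(df), outcome)])
  ds <- structure(list(X = X, y = as.numeric(y), feature_names = colnames(X)),
                  class = "aiwrap_dataset")
  ds
}

#' Write a dataset as delimited text
#'
#' @param dataset an `aiwrap_dataset`.
#' @param path output file (`.tsv`/`.tab` writes tab-separated).
#' @param outcome name for the outcome column.
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path, outcome = "y") {
  df <- data.frame(dataset$X, check.names = FALSE)
  df[[outcome]] <- dataset$y
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a pipeline result to JSON
#'
#' Writes the nested selections, final-model coefficients and fit counters
#' as a versioned JSON document.
#'
#' @param result an `aiwrap_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  out <- list(
    schema = 1,
    variant = result$variant,
    q_wrap = result$q_wrap,
    q_embed = result$q_embed,
    q_final = result$q_final,
    model = list(technique = result$model$technique,
                 intercept = result$model$intercept,
                 coefficients = as.list(result$model$coefficients),
                 hyperparameters = result$model$hyperparameters,
                 cv_rmse = result$model$cv_rmse),
    fit_counts = result$fit_counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
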
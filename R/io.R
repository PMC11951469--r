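#' Read a survival dataset from delimited text
#'
#' Expects a header row; lines starting with `#` are treated as comments
#' (run manifests embedded by [write_dataset()]). Validation is strict and
#' reports offending row numbers.
#'
#' @param path CSV file path.
#' @param time_col,event_col,treatment_col Column names.
#' @param covariate_cols Covariate column names; default: every other
#'   numeric column.
#' @return A [survival_dataset()].
#' @export
read_dataset <- function(path, time_col = "time", event_col = "event",
                         treatment_col = "treatment", covariate_cols = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c(time_col, event_col, treatment_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(covariate_cols)) {
    others <- setdiff(names(df), c(time_col, event_col, treatment_col))
    covariate_cols <- others[vapply(df[others], is.numeric, logical(1))]
    if (!length(covariate_cols)) {
      stop("no numeric covariate columns found", call. = FALSE)
    }
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(!ok), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  used <- df[, c(time_col, event_col, treatment_col, covariate_cols)]
  bad_row(stats::complete.cases(used), "missing values")
  bad_row(is.finite(df[[time_col]]) & df[[time_col]] > 0, "non-positive time")
  bad_row(df[[event_col]] %in% c(0, 1), "non-binary event indicator")
  bad_row(df[[treatment_col]] %in% c(0, 1), "non-binary treatment indicator")
  survival_dataset(df[[time_col]], df[[event_col]], df[[treatment_col]],
                   as.matrix(df[covariate_cols]))
}

#' Write a survival dataset as CSV
#'
#' Columns `time`, `event`, `treatment`, then covariates. An optional
#' manifest is embedded as `#`-prefixed comment lines so every output file
#' carries its resolved configuration; [read_dataset()] skips them.
#'
#' @param data A [survival_dataset()].
#' @param path Output path.
#' @param manifest Optional named list recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, manifest = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(time = data$times, event = data$events,
                   treatment = data$treatment)
  df <- cbind(df, as.data.frame(data$covariates))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) {
    writeLines(paste0("# ", manifest_lines(manifest)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

manifest_lines <- function(manifest) {
  vapply(names(manifest), function(nm) {
    sprintf("%s=%s", nm, paste(format(manifest[[nm]], digits = 15), collapse = ","))
  }, character(1))
}

write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

write_tsv_with_manifest <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", manifest_lines(manifest)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
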
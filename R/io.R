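# Delimited-text I/O for feature matrices, with header auto-detection, an
# optional label column, and strict rejection of non-numeric or missing
# cells (no imputation: variables with missing values are expected to be
# removed upstream).

#' Read a feature matrix from delimited text
#'
#' The header row is auto-detected: if any cell of the first row fails to
#' parse as a number, it is taken as column names. Every remaining cell must
#' parse as a finite number; the first offending row/column is named in the
#' error. An optional label column is split off and returned separately.
#'
#' @param path CSV/TSV file path.
#' @param delimiter field delimiter (default comma).
#' @param labelCol name or index of a label column to split off, or `NULL`.
#' @return A list with `x` (numeric matrix) and `labels` (vector or `NULL`).
#' @export
readFeatureMatrix <- function(path, delimiter = ",", labelCol = NULL) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  first <- utils::read.table(path, sep = delimiter, nrows = 1L,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  hasHeader <- anyNA(suppressWarnings(as.numeric(unlist(first))))
  df <- utils::read.table(path, sep = delimiter, header = hasHeader,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!hasHeader) colnames(df) <- paste0("V", seq_len(ncol(df)))

  labels <- NULL
  if (!is.null(labelCol)) {
    j <- if (is.numeric(labelCol)) as.integer(labelCol)
         else match(labelCol, colnames(df))
    if (is.na(j) || j < 1L || j > ncol(df))
      stop(sprintf("label column '%s' not found", labelCol))
    labels <- df[[j]]
    df <- df[, -j, drop = FALSE]
  }

  x <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf(
        "non-numeric or missing value at row %d, column '%s'",
        bad[1L], colnames(df)[j]))
    x[, j] <- v
  }
  list(x = x, labels = labels)
}

#' Write a feature matrix as delimited text
#'
#' @param x numeric matrix or data.frame.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @param labels optional label vector appended as a final `label` column.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(x, path, delimiter = ",", labels = NULL) {
  x <- asFeatureMatrix(x)
  df <- as.data.frame(x)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("'labels' length must match the number of rows")
    df$label <- labels
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a provenance sidecar for an output file
#'
#' Records the configuration, seed and package version alongside an output
#' so a run can be reproduced exactly. Written as `<path>.json`.
#'
#' @param path the output file the sidecar describes.
#' @param config named list of settings to record.
#' @return The sidecar path, invisibly.
#' @export
writeSidecar <- function(path, config) {
  side <- paste0(path, ".json")
  doc <- list(tool = "glscale",
              version = as.character(utils::packageVersion("glscale")),
              config = config)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"), side)
  invisible(side)
}
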
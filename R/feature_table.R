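#' Construct a feature-abundance table
#'
#' The hub container between preprocessing, quality control and statistics:
#' a features-by-samples abundance matrix (NA allowed) plus per-sample
#' metadata (a group label and numeric covariates).
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param sample_meta Optional data frame keyed by sample id (rownames
#'   matching `colnames(values)`); a `group` column, if present, is treated
#'   as the primary factor.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) && nrow(values))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!setequal(rownames(sample_meta), colnames(values)))
      stop("sample_meta rownames must match sample ids")
    sample_meta <- sample_meta[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d features x %d samples%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$sample_meta)) "" else
                paste0(", meta: ", paste(names(x$sample_meta), collapse = ", "))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from TSV/CSV
#'
#' Features in rows; first column feature id, header row sample ids.
#'
#' @param path Abundance file path.
#' @param meta_path Optional sample-metadata file (first column sample id).
#' @param sep Field separator (default tab).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, meta_path = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
  meta <- if (!is.null(meta_path))
    read.delim(meta_path, sep = sep, row.names = 1, check.names = FALSE)
  feature_table(as.matrix(df), sample_meta = meta)
}

#' Write a feature table to TSV
#'
#' @param table A [feature_table()].
#' @param path Output abundance file.
#' @param meta_path Optional output path for sample metadata.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, meta_path = NULL, sep = "\t") {
  df <- data.frame(feature_id = rownames(table$values), table$values,
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(table$sample_meta)) {
    md <- data.frame(sample_id = rownames(table$sample_meta),
                     table$sample_meta, check.names = FALSE)
    write.table(md, meta_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
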
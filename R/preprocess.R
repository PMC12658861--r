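#' Pareto scaling
#'
#' Per feature, subtracts the mean and divides by the square root of the
#' (sample) standard deviation. Tempering by sqrt(sd) rather than sd
#' reduces the dominance of high-abundance metabolites while preserving
#' more of the original data structure than unit-variance scaling. NA
#' positions are preserved; a zero-variance feature is centered only, with
#' a warning.
#'
#' @param table A [feature_table()].
#' @return The scaled [feature_table()].
#' @export
pareto_scale <- function(table) {
  v <- table$values
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("feature ", rownames(v)[i],
                          " has fewer than 2 non-missing values")
    m <- mean(x[ok]); s <- sd(x[ok])
    if (s == 0) {
      warning("feature ", rownames(v)[i], " has zero sd; centered only")
      v[i, ] <- x - m
    } else {
      v[i, ] <- (x - m) / sqrt(s)
    }
  }
  feature_table(v, table$sample_meta)
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their (average-tied) ranks
#' using the Blom offset: `qnorm((rank - c) / (n - 2c + 1))` with
#' `c = 3/8` by default. NA is preserved.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @param c Rank offset constant (default `3/8`, the Blom convention).
#' @return Transformed vector; an all-tied input maps to all zeros with a
#'   warning.
#' @export
rint <- function(values, c = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("rint needs at least 2 non-missing values")
  x <- values[ok]
  if (length(unique(x)) == 1L)
    warning("all values tied; rank-based transform is identically zero")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - c) / (n - 2 * c + 1))
  out
}

#' Apply the rank-based inverse normal transform per feature
#'
#' @param table A [feature_table()].
#' @param c Rank offset constant, see [rint()].
#' @return Transformed [feature_table()].
#' @export
rint_table <- function(table, c = 3 / 8) {
  v <- table$values
  for (i in seq_len(nrow(v))) v[i, ] <- rint(v[i, ], c = c)
  feature_table(v, table$sample_meta)
}

#' Internal-standard normalization
#'
#' Divides every feature, per sample, by the abundance of the designated
#' internal-standard feature (which must be complete and nonzero).
#'
#' @param table A [feature_table()].
#' @param is_feature Feature id of the internal standard.
#' @return Normalized [feature_table()] (the IS row becomes all ones).
#' @export
normalize_internal_standard <- function(table, is_feature) {
  v <- table$values
  if (!is_feature %in% rownames(v)) stop("internal standard ", is_feature,
                                         " not found")
  is_row <- v[is_feature, ]
  bad <- which(is.na(is_row) | is_row == 0)
  if (length(bad))
    stop("internal standard is missing or zero in sample(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  feature_table(sweep(v, 2, is_row, "/"), table$sample_meta)
}

#' Logarithmic transform
#'
#' Elementwise `log_base(x + offset)`.
#'
#' @param table A [feature_table()].
#' @param base Logarithm base (default 2).
#' @param offset Added before the log (default 0).
#' @return Transformed [feature_table()].
#' @export
log_transform <- function(table, base = 2, offset = 0) {
  v <- table$values + offset
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("log transform undefined at feature/sample: ",
         paste(sprintf("%s/%s", rownames(table$values)[bad[, 1]],
                       colnames(table$values)[bad[, 2]]), collapse = ", "))
  feature_table(log(v, base = base), table$sample_meta)
}
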
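#' Per-feature quality metrics
#'
#' For each feature: fraction of missing entries, fraction of zeros among
#' the non-missing entries, and the across-sample signal-to-noise ratio
#' (mean/sd over non-missing values; `Inf` for a constant nonzero feature,
#' `NA` when fewer than 2 values remain).
#'
#' @param table A [feature_table()] with at least 2 samples.
#' @return Data frame with columns `feature_id`, `missing_rate`,
#'   `zero_rate`, `sn`.
#' @export
peak_metrics <- function(table) {
  v <- table$values
  if (ncol(v) < 2) stop("peak_metrics needs at least 2 samples")
  res <- data.frame(feature_id = rownames(v),
                    missing_rate = NA_real_, zero_rate = NA_real_,
                    sn = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    res$missing_rate[i] <- mean(is.na(x))
    ok <- x[!is.na(x)]
    res$zero_rate[i] <- if (length(ok)) mean(ok == 0) else NA_real_
    if (length(ok) >= 2) {
      s <- sd(ok)
      res$sn[i] <- if (s == 0) Inf else mean(ok) / s
    }
  }
  res
}

#' Filter features on quality metrics
#'
#' Keeps features with `missing_rate <= max_missing`, `zero_rate <=
#' max_zero` and `sn >= min_sn` (features with undefined S/N are kept only
#' when `min_sn <= 0`). Idempotent. The removal report (ids and reasons,
#' thresholds used) is attached as attribute `"qc_report"`.
#'
#' @param table A [feature_table()].
#' @param max_missing Maximum missing rate in `[0, 1]` (default 1).
#' @param max_zero Maximum zero rate in `[0, 1]` (default 1).
#' @param min_sn Minimum signal-to-noise ratio (default 0).
#' @return Filtered [feature_table()] (possibly empty, with a warning).
#' @export
filter_peaks <- function(table, max_missing = 1, max_zero = 1, min_sn = 0) {
  if (max_missing < 0 || max_missing > 1 || max_zero < 0 || max_zero > 1)
    stop("rate thresholds must lie in [0, 1]")
  m <- peak_metrics(table)
  fail_missing <- m$missing_rate > max_missing
  fail_zero <- !is.na(m$zero_rate) & m$zero_rate > max_zero
  fail_sn <- if (min_sn > 0) is.na(m$sn) | m$sn < min_sn
             else rep(FALSE, nrow(m))
  keep <- !(fail_missing | fail_zero | fail_sn)
  reasons <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(if (fail_missing[i]) "missing_rate",
            if (fail_zero[i]) "zero_rate",
            if (fail_sn[i]) "sn"), collapse = "+")
  }, character(1))
  if (!any(keep)) warning("all features removed by quality filters")
  out <- feature_table(table$values[keep, , drop = FALSE], table$sample_meta)
  attr(out, "qc_report") <- list(
    retained = m$feature_id[keep],
    removed = data.frame(feature_id = m$feature_id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE),
    thresholds = list(max_missing = max_missing, max_zero = max_zero,
                      min_sn = min_sn),
    metrics = m)
  out
}

#' Sample-to-sample correlation distance
#'
#' `1 - cor` between sample profiles, pairwise-complete on NA. Kendall uses
#' the tie-corrected tau-b.
#'
#' @param table A [feature_table()] with at least 3 samples.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
sample_distance <- function(table, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (ncol(table$values) < 3) stop("sample_distance needs at least 3 samples")
  d <- 1 - cor(table$values, method = method, use = "pairwise.complete.obs")
  diag(d) <- 0
  d
}

#' Filter outlier samples by clustering
#'
#' Average-linkage hierarchical clustering on the correlation-distance
#' matrix; samples that remain singleton clusters when the dendrogram is
#' cut at height `cut` are removed as outliers. The report (retained and
#' removed sample ids, the dendrogram) is attached as attribute
#' `"qc_report"`.
#'
#' @param table A [feature_table()].
#' @param method Correlation method, see [sample_distance()].
#' @param cut Dendrogram cut height, > 0.
#' @return Filtered [feature_table()].
#' @export
filter_samples <- function(table, method = c("pearson", "spearman", "kendall"),
                           cut) {
  method <- match.arg(method)
  if (cut <= 0) stop("cut must be > 0")
  d <- sample_distance(table, method)
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = cut)
  sizes <- tabulate(cl)          # cluster sizes; singletons are outliers
  keep <- sizes[cl] > 1
  if (!any(keep)) {
    warning("all samples are singleton clusters at this cut; none removed")
    keep <- rep(TRUE, length(cl))
  }
  out <- feature_table(table$values[, keep, drop = FALSE],
                       if (is.null(table$sample_meta)) NULL
                       else table$sample_meta[keep, , drop = FALSE])
  attr(out, "qc_report") <- list(
    retained = colnames(table$values)[keep],
    removed = colnames(table$values)[!keep],
    cut = cut, method = method, hclust = hc)
  out
}
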
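#' Per-feature ANCOVA association
#'
#' Fits `value ~ trait + covariates` by least squares for every feature and
#' reports the trait term's effect size (between-group difference for a
#' two-level factor trait), standard error, t statistic and p-value, with
#' Benjamini-Hochberg adjustment across features. Per-feature residuals are
#' attached as attribute `"residuals"` (features x samples, NA where the
#' sample was incomplete).
#'
#' @param table A [feature_table()] with sample metadata.
#' @param trait Name of the trait column in `sample_meta` (factor/character
#'   for a group comparison, numeric for a quantitative trait).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return Data frame with columns `feature_id`, `beta`, `se`, `t`, `p`,
#'   `p_fdr`; skipped (rank-deficient) features carry NA and a warning is
#'   emitted.
#' @export
ancova <- function(table, trait, covariates = character(0)) {
  meta <- table$sample_meta
  if (is.null(meta)) stop("table has no sample metadata")
  if (!trait %in% names(meta)) stop("trait column ", trait, " not in metadata")
  if (!all(covariates %in% names(meta)))
    stop("covariate(s) missing from metadata: ",
         paste(setdiff(covariates, names(meta)), collapse = ", "))
  tr <- meta[[trait]]
  if (is.character(tr)) tr <- factor(tr)
  rhs <- data.frame(..trait = tr, meta[covariates], check.names = FALSE)
  # design rank check on complete metadata: a covariate collinear with the
  # trait makes the trait term unidentifiable for every feature
  X_all <- model.matrix(~ ., data = rhs)
  v <- table$values
  n_feat <- nrow(v)
  res <- data.frame(feature_id = rownames(v), beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  resid_mat <- matrix(NA_real_, n_feat, ncol(v),
                      dimnames = dimnames(v))
  trait_col <- 2L  # intercept first, trait term second in the design
  min_n <- length(covariates) + 2L
  for (i in seq_len(n_feat)) {
    y <- v[i, ]
    ok <- !is.na(y) & complete.cases(rhs)
    if (sum(ok) < min_n + 1L) {
      warning("feature ", rownames(v)[i], " skipped: too few complete samples")
      next
    }
    X <- X_all[ok, , drop = FALSE]
    if (qr(X)$rank < ncol(X)) {
      warning("feature ", rownames(v)[i], " skipped: rank-deficient design")
      next
    }
    fit <- lm.fit(X, y[ok])
    rdf <- fit$df.residual
    if (rdf < 1) {
      warning("feature ", rownames(v)[i], " skipped: no residual df")
      next
    }
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / rdf
    XtX_inv <- solve(crossprod(X))
    se <- sqrt(sigma2 * XtX_inv[trait_col, trait_col])
    res$beta[i] <- fit$coefficients[trait_col]
    res$se[i] <- se
    res$t[i] <- res$beta[i] / se
    res$p[i] <- 2 * pt(abs(res$t[i]), rdf, lower.tail = FALSE)
    resid_mat[i, ok] <- fit$residuals
  }
  res$p_fdr <- p.adjust(res$p, method = "BH")
  attr(res, "residuals") <- resid_mat
  res
}

#' Covariate-adjusted residuals
#'
#' Per feature, residuals from `value ~ covariates` (the trait excluded),
#' for use as inputs to PLS/PLS-DA. With no covariates this reduces to
#' mean-centering. Residuals are orthogonal to every covariate by
#' construction.
#'
#' @param table A [feature_table()].
#' @param covariates Character vector of covariate columns in `sample_meta`.
#' @return A [feature_table()] of residuals (NA where a sample was
#'   incomplete).
#' @export
residualize <- function(table, covariates = character(0)) {
  meta <- table$sample_meta
  if (length(covariates)) {
    if (is.null(meta)) stop("table has no sample metadata")
    if (!all(covariates %in% names(meta)))
      stop("covariate(s) missing from metadata")
    rhs <- meta[covariates]
    X_all <- model.matrix(~ ., data = rhs)
  } else {
    rhs <- data.frame(row.names = colnames(table$values))
    X_all <- matrix(1, ncol(table$values), 1)
  }
  v <- table$values
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) {
    y <- v[i, ]
    ok <- !is.na(y) & (if (ncol(rhs)) complete.cases(rhs) else TRUE)
    if (sum(ok) <= ncol(X_all)) {
      warning("feature ", rownames(v)[i], " skipped: too few complete samples")
      next
    }
    fit <- lm.fit(X_all[ok, , drop = FALSE], y[ok])
    out[i, ok] <- fit$residuals
  }
  feature_table(out, meta)
}

#' Dual filtering of features
#'
#' Intersects the ANCOVA FDR filter (`p_fdr < p_fdr_max`) with the
#' `top_k` features ranked by VIP score. Ties at the VIP boundary are
#' broken deterministically by feature id.
#'
#' @param ancova_results Data frame from [ancova()].
#' @param model A fitted [pls_fit()] model whose predictors are the same
#'   feature universe.
#' @param p_fdr_max FDR threshold (default 0.05).
#' @param top_k Number of top-VIP features (default 10).
#' @return Character vector of selected feature ids (possibly empty, with a
#'   warning).
#' @export
dual_filter <- function(ancova_results, model, p_fdr_max = 0.05, top_k = 10) {
  vips <- vip(model)
  ids <- names(vips)
  if (is.null(ids)) stop("model predictors are unnamed")
  if (!all(ids %in% ancova_results$feature_id) ||
      !all(ancova_results$feature_id %in% ids))
    stop("feature universes of ancova results and PLS model differ")
  ord <- order(-vips, ids)           # VIP desc, id asc on ties
  top <- ids[ord][seq_len(min(top_k, length(ids)))]
  sig <- ancova_results$feature_id[!is.na(ancova_results$p_fdr) &
                                     ancova_results$p_fdr < p_fdr_max]
  sel <- sort(intersect(top, sig))
  if (!length(sel)) warning("dual filter selected no features")
  sel
}
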
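#' Fit a PLS or PLS-DA model by NIPALS
#'
#' Partial least squares regression on column-centered, unit-variance
#' scaled data. A factor/character response switches to discriminant mode
#' (PLS-DA) with one-hot dummy coding of the classes. Each latent variable
#' is a linear combination of the predictors; scores, weights and loadings
#' are returned together with cumulative R2X, R2Y and the full-fit RMSEE.
#'
#' @param X Numeric matrix, samples x predictors (named columns
#'   recommended).
#' @param Y Numeric matrix/vector (regression) or factor/character vector
#'   (discriminant mode).
#' @param A Number of latent components (truncated with a warning if it
#'   exceeds the effective rank).
#' @param scale Scale predictors and responses to unit variance (default
#'   TRUE); centering is always applied.
#' @return An object of class `pls_model` with elements `scores`,
#'   `weights`, `loadings`, `y_loadings`, `r2x`, `r2y` (cumulative
#'   fractions), `rmsee`, `coefficients` (on the original scale via
#'   [predict.pls_model()]), `vip` and bookkeeping needed for prediction.
#' @export
pls_fit <- function(X, Y, A = 2, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  discriminant <- is.factor(Y) || is.character(Y)
  if (discriminant) {
    f <- factor(Y)
    classes <- levels(f)
    Ymat <- sapply(classes, function(cl) as.numeric(f == cl))
    colnames(Ymat) <- classes
  } else {
    Ymat <- as.matrix(Y)
    classes <- NULL
    if (is.null(colnames(Ymat))) colnames(Ymat) <- paste0("Y", seq_len(ncol(Ymat)))
  }
  n <- nrow(X)
  if (nrow(Ymat) != n) stop("X and Y disagree on sample count")
  if (n < 3) stop("PLS needs at least 3 samples")
  if (anyNA(X) || anyNA(Ymat)) stop("X and Y must be complete (no NA)")

  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  drop_idx <- which(x_scale == 0 | is.na(x_scale))
  if (length(drop_idx)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    x_center <- x_center[-drop_idx]
    x_scale <- x_scale[-drop_idx]
  }
  if (!ncol(X)) stop("no usable predictors")
  y_center <- colMeans(Ymat)
  y_scale <- if (scale) apply(Ymat, 2, sd) else rep(1, ncol(Ymat))
  y_scale[y_scale == 0] <- 1
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  F_ <- sweep(sweep(Ymat, 2, y_center), 2, y_scale, "/")
  ssx0 <- sum(E^2); ssy0 <- sum(F_^2)

  max_A <- qr(E)$rank
  if (A > max_A) {
    warning("A reduced from ", A, " to rank ", max_A)
    A <- max_A
  }
  p <- ncol(E); q <- ncol(F_)
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, q, A)
  Tm <- matrix(0, n, A); ss_y_comp <- numeric(A)
  for (a in seq_len(A)) {
    if (sum(F_^2) < 1e-12 * ssy0 || sum(E^2) < 1e-12 * ssx0) {
      warning("response/predictor residual exhausted; A truncated to ", a - 1L)
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      C <- C[, seq_len(A), drop = FALSE]; Tm <- Tm[, seq_len(A), drop = FALSE]
      ss_y_comp <- ss_y_comp[seq_len(A)]
      break
    }
    u <- F_[, which.max(apply(F_, 2, var)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (iter in 1:500) {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      t_ <- drop(E %*% w)
      cvec <- drop(crossprod(F_, t_)) / sum(t_^2)
      u <- drop(F_ %*% cvec) / sum(cvec^2)
      if (sum((t_ - t_old)^2) < 1e-14 * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    fit_y <- tcrossprod(t_, cvec)
    ss_y_comp[a] <- sum(fit_y^2)
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - fit_y
    W[, a] <- w; P[, a] <- p_; C[, a] <- cvec; Tm[, a] <- t_
  }
  rownames(W) <- rownames(P) <- colnames(X)
  r2x <- cumsum(vapply(seq_len(A), function(a)
    sum((Tm[, a] %o% P[, a])^2), numeric(1))) / ssx0
  r2y <- cumsum(ss_y_comp) / ssy0

  model <- structure(list(
    A = A, scores = Tm, weights = W, loadings = P, y_loadings = C,
    r2x = r2x, r2y = r2y, ss_y_comp = ss_y_comp,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    classes = classes, y_names = colnames(Ymat),
    n = n, scale = scale), class = "pls_model")
  # full-fit estimation error: RMSEE = sqrt(RSS / (n - A - 1)) on the
  # (scaled) response, the convention of the multivariate package this
  # model family follows
  Yhat <- predict(model, X)
  if (discriminant) {
    Ynum <- sapply(model$classes, function(cl) as.numeric(factor(Y) == cl))
  } else Ynum <- Ymat
  rss <- sum((Ynum - Yhat)^2)
  model$rmsee <- sqrt(rss / max(1, (n - A - 1)))
  model$vip <- vip(model)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %s mode>\n", x$A,
              if (is.null(x$classes)) "regression" else "discriminant"))
  cat(sprintf("  R2X(cum) %.4f  R2Y(cum) %.4f  RMSEE %.4f\n",
              x$r2x[x$A], x$r2y[x$A], x$rmsee))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Samples x predictors matrix on the original scale.
#' @param type `"response"` (numeric predictions of the response/dummy
#'   columns) or `"class"` (discriminant mode only: class of the largest
#'   predicted dummy column, ties to the first class).
#' @param ... Unused.
#' @return Matrix of predictions, or a factor for `type = "class"`.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  nd <- as.matrix(newdata)
  if (is.null(colnames(nd))) colnames(nd) <- paste0("X", seq_len(ncol(nd)))
  nd <- nd[, names(object$x_center), drop = FALSE]
  Xs <- sweep(sweep(nd, 2, object$x_center), 2, object$x_scale, "/")
  W <- object$weights; P <- object$loadings; C <- object$y_loadings
  R <- W %*% solve(crossprod(P, W))      # X-rotations: T = Xs %*% R
  B <- R %*% t(C)
  Yhat_s <- Xs %*% B
  Yhat <- sweep(sweep(Yhat_s, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(Yhat) <- object$y_names
  if (type == "class") {
    if (is.null(object$classes)) stop("not a discriminant model")
    idx <- apply(Yhat, 1, which.max)     # ties resolve to the first class
    return(factor(object$classes[idx], levels = object$classes))
  }
  Yhat
}

#' Variable importance in projection
#'
#' Standard VIP: `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with
#' unit-norm component weights and `SS_a` the response variance explained
#' by component `a`. Satisfies `sum(VIP^2) == p`.
#'
#' @param model A fitted `pls_model`.
#' @return Named vector of per-predictor VIP scores.
#' @export
vip <- function(model) {
  W <- model$weights
  ss <- model$ss_y_comp
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(p * drop(wn2 %*% ss) / sum(ss))
  names(v) <- rownames(W)
  v
}

#' Cross-validated predictive accuracy (Q2Y) and RMSEE
#'
#' K-fold cross-validation of a PLS/PLS-DA model:
#' `Q2Y = 1 - PRESS / TSS` over held-out predictions (folds stratified by
#' class in discriminant mode; shuffling is seeded and deterministic), plus
#' the full-fit RMSEE.
#'
#' @param X Samples x predictors matrix.
#' @param Y Response (as in [pls_fit()]).
#' @param A Number of components.
#' @param folds Number of folds (default 7).
#' @param seed Integer seed for the fold shuffle.
#' @param scale Passed to [pls_fit()].
#' @return List with `q2y`, `rmsee` and the fold assignment.
#' @export
cross_validate <- function(X, Y, A = 2, folds = 7, seed = 1, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("folds must lie in [2, n]")
  discriminant <- is.factor(Y) || is.character(Y)
  fold_id <- with_seed(seed, {
    if (discriminant) {
      f <- factor(Y)
      if (any(tabulate(f) < folds))
        stop("cannot stratify: a class has fewer members than folds")
      id <- integer(n)
      for (cl in levels(f)) {
        idx <- sample(which(f == cl))
        id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      id
    } else rep_len(seq_len(folds), n)[sample(n)]
  })
  if (discriminant) {
    fY <- factor(Y)
    Ynum <- sapply(levels(fY), function(cl) as.numeric(fY == cl))
  } else Ynum <- as.matrix(Y)
  press <- 0; tss <- 0
  for (k in seq_len(folds)) {
    test <- fold_id == k
    m <- pls_fit(X[!test, , drop = FALSE],
                 if (discriminant) factor(Y[!test]) else
                   Ynum[!test, , drop = FALSE],
                 A = A, scale = scale)
    yhat <- suppressWarnings(predict(m, X[test, , drop = FALSE]))
    ytest <- Ynum[test, , drop = FALSE]
    press <- press + sum((ytest - yhat)^2)
    ybar <- colMeans(Ynum[!test, , drop = FALSE])
    tss <- tss + sum(sweep(ytest, 2, ybar)^2)
  }
  full <- pls_fit(X, Y, A = A, scale = scale)
  list(q2y = 1 - press / tss, rmsee = full$rmsee, fold_id = fold_id)
}
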
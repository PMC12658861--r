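#' Construct a calibration standard series
#'
#' @param concentration Numeric vector of known concentrations (> 0), e.g.
#'   ppb.
#' @param response Instrument responses (peak abundances), same length.
#' @param compound Compound name label.
#' @return An object of class `standard_series`.
#' @export
standard_series <- function(concentration, response, compound = "") {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response))
    stop("concentration and response must have the same length")
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  structure(list(points = data.frame(x = concentration, y = response),
                 compound = as.character(compound)),
            class = "standard_series")
}

#' Read a standards table
#'
#' TSV with columns `compound`, `concentration`, `response` (an optional
#' `replicate` column is carried through untouched).
#'
#' @param path File path.
#' @return Named list of [standard_series()], one per compound.
#' @export
read_standards <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("compound", "concentration", "response") %in% names(df)))
    stop("standards table needs columns compound, concentration, response")
  lapply(split(df, df$compound), function(s)
    standard_series(s$concentration, s$response, compound = s$compound[1]))
}

cal_weights <- function(x, scheme) {
  switch(scheme, "1" = rep(1, length(x)), "1/x" = 1 / x, "1/x^2" = 1 / x^2,
         stop("unknown weight scheme: ", scheme))
}

min_points <- function(form) if (form == "linear") 4L else 5L

#' Weighted least-squares calibration fit
#'
#' Fits `response ~ concentration` (linear) or with an added quadratic
#' term, with weights 1, 1/x or 1/x^2. R-squared is computed on the
#' weighted scale (weighted residual and total sums of squares about the
#' weighted mean); adjusted R-squared uses
#' `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param series A [standard_series()] (or a data frame with `x`, `y`).
#' @param form `"linear"` or `"quadratic"`.
#' @param weight_scheme `"1"`, `"1/x"` or `"1/x^2"`.
#' @return An object of class `calibration_fit` with the `lm` fit,
#'   coefficients, `r2`, `adj_r2`, and the fitted x/y ranges.
#' @export
fit_wls <- function(series, form = c("linear", "quadratic"),
                    weight_scheme = c("1", "1/x", "1/x^2")) {
  form <- match.arg(form)
  weight_scheme <- match.arg(weight_scheme)
  pts <- if (inherits(series, "standard_series")) series$points
         else as.data.frame(series)
  n <- nrow(pts)
  p <- if (form == "linear") 1L else 2L
  if (n < p + 3L)
    stop("need at least ", p + 3L, " points for a ", form, " fit")
  if (form == "quadratic" && length(unique(pts$x)) < 3L)
    stop("quadratic fit needs at least 3 distinct concentrations")
  w <- cal_weights(pts$x, weight_scheme)
  df_fit <- data.frame(x = pts$x, y = pts$y, w = w)
  fit <- if (form == "linear") lm(y ~ x, data = df_fit, weights = w)
         else lm(y ~ x + I(x^2), data = df_fit, weights = w)
  res <- residuals(fit)
  ywbar <- weighted.mean(pts$y, w)
  r2 <- 1 - sum(w * res^2) / sum(w * (pts$y - ywbar)^2)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(fit = fit, form = form, weight_scheme = weight_scheme,
                 coefficients = unname(coef(fit)), points = pts, weights = w,
                 r2 = r2, adj_r2 = adj_r2,
                 x_range = range(pts$x), y_range = range(fitted(fit)),
                 compound = if (inherits(series, "standard_series"))
                   series$compound else ""),
            class = "calibration_fit")
}

#' Flag outlying calibration standards
#'
#' Three rules: `cooks_d` flags points with Cook's distance above `4/n`;
#' `ci` flags points falling outside their own 95% prediction interval,
#' assessed with the point deleted from the fit (externally studentized
#' residuals), so a gross outlier cannot mask itself by inflating the
#' residual variance; `bias` flags points whose back-calculated
#' concentration deviates from the nominal one by more than 20% relative
#' error. A numerically exact fit (R-squared within 1e-10 of 1) has no
#' outliers under any rule.
#'
#' @param model A [fit_wls()] fit.
#' @param method `"cooks_d"`, `"ci"` or `"bias"`.
#' @param cooks_threshold Cook's D cutoff (default `4/n`).
#' @param ci_level Prediction-band coverage (default 0.95).
#' @param bias_max Maximum back-calculated relative error in percent
#'   (default 20).
#' @return Integer vector of flagged point indices (possibly empty).
#' @export
detect_outliers <- function(model, method = c("cooks_d", "ci", "bias"),
                            cooks_threshold = NULL, ci_level = 0.95,
                            bias_max = 20) {
  method <- match.arg(method)
  pts <- model$points
  n <- nrow(pts)
  p <- if (model$form == "linear") 1L else 2L
  if (n <= p + 1L) stop("too few points for outlier diagnostics")
  if (model$r2 > 1 - 1e-10) return(integer(0))
  if (method == "cooks_d") {
    if (is.null(cooks_threshold)) cooks_threshold <- 4 / n
    d <- cooks.distance(model$fit)
    return(which(unname(d) > cooks_threshold))
  }
  if (method == "ci") {
    rs <- rstudent(model$fit)
    crit <- qt(1 - (1 - ci_level) / 2, df = n - (p + 1) - 1)
    return(which(unname(abs(rs)) > crit))
  }
  # bias: back-calculate each standard with the current model
  back <- vapply(seq_len(n), function(i) {
    est <- tryCatch(
      suppressWarnings(estimate_concentration(as_calibration_model(model),
                                              pts$y[i])),
      error = function(e) NA_real_)
    est
  }, numeric(1))
  rel <- abs(back - pts$x) / pts$x * 100
  which(is.na(back) | rel > bias_max)
}

as_calibration_model <- function(fit, removed_x = numeric(0),
                                 outlier_method = NA_character_,
                                 feasible = TRUE, iterations = 0L) {
  structure(list(form = fit$form, weight_scheme = fit$weight_scheme,
                 outlier_method = outlier_method,
                 coefficients = fit$coefficients,
                 retained_x = sort(unique(fit$points$x)),
                 removed_x = sort(unique(removed_x)),
                 r2 = fit$r2, adj_r2 = fit$adj_r2,
                 x_range = fit$x_range, y_range = fit$y_range,
                 feasible = feasible, iterations = iterations,
                 compound = fit$compound, fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s: %s, w=%s, outliers=%s | R2 %.4f adj %.4f | retained %s>\n",
              x$compound, x$form, x$weight_scheme, x$outlier_method,
              x$r2, x$adj_r2, paste(x$retained_x, collapse = ";")))
  invisible(x)
}

#' Build calibration curves across model scenarios
#'
#' For every combination of regression form, weighting scheme and outlier
#' rule, iterates flag -> remove (all flagged at once) -> refit until no
#' point is flagged, `max_iter` passes are reached, or removal would drop
#' below the minimum point count (4 linear / 5 quadratic; such scenarios
#' are marked infeasible, not fatal). Scenarios are ranked by adjusted
#' R-squared descending; exact ties break toward fewer removed points,
#' then the simpler (linear) form.
#'
#' @param series A [standard_series()].
#' @param forms Forms to try (default both).
#' @param weights Weight schemes to try (default all three).
#' @param methods Outlier rules to try (default all three).
#' @param max_iter Maximum flag/refit passes per scenario (default 5).
#' @return List of `calibration_model` objects, best first; the scenario
#'   summary table is attached as attribute `"scenarios"`.
#' @export
build_calibration <- function(series,
                              forms = c("linear", "quadratic"),
                              weights = c("1", "1/x", "1/x^2"),
                              methods = c("cooks_d", "ci", "bias"),
                              max_iter = 5) {
  if (!length(forms) || !length(weights) || !length(methods))
    stop("scenario grid is empty")
  models <- list()
  for (form in forms) for (ws in weights) for (om in methods) {
    pts <- series$points
    removed <- numeric(0)
    feasible <- TRUE
    it <- 0L
    fit <- NULL
    repeat {
      if (nrow(pts) < min_points(form)) { feasible <- FALSE; break }
      fit <- tryCatch(fit_wls(standard_series(pts$x, pts$y, series$compound),
                              form, ws),
                      error = function(e) NULL)
      if (is.null(fit)) { feasible <- FALSE; break }
      if (it >= max_iter) break
      flagged <- tryCatch(detect_outliers(fit, om),
                          error = function(e) integer(0))
      if (!length(flagged)) break
      if (nrow(pts) - length(flagged) < min_points(form)) break
      removed <- c(removed, pts$x[flagged])
      pts <- pts[-flagged, , drop = FALSE]
      it <- it + 1L
    }
    if (feasible && !is.null(fit)) {
      models[[length(models) + 1L]] <-
        as_calibration_model(fit, removed_x = removed, outlier_method = om,
                             feasible = TRUE, iterations = it)
    } else {
      models[[length(models) + 1L]] <- structure(
        list(form = form, weight_scheme = ws, outlier_method = om,
             coefficients = NULL, retained_x = numeric(0),
             removed_x = sort(unique(removed)), r2 = NA_real_,
             adj_r2 = NA_real_, feasible = FALSE, iterations = it,
             compound = series$compound),
        class = "calibration_model")
    }
  }
  form_rank <- vapply(models, function(m)
    if (m$form == "linear") 1L else 2L, integer(1))
  key_adj <- vapply(models, function(m)
    if (isTRUE(m$feasible)) m$adj_r2 else -Inf, numeric(1))
  n_removed <- vapply(models, function(m) length(m$removed_x), numeric(1))
  ord <- order(-key_adj, n_removed, form_rank)
  models <- models[ord]
  scen <- do.call(rbind, lapply(models, function(m) data.frame(
    compound = m$compound, form = m$form, weight = m$weight_scheme,
    outlier_method = m$outlier_method,
    retained = paste(m$retained_x, collapse = ";"),
    removed = paste(m$removed_x, collapse = ";"),
    r2 = m$r2, adj_r2 = m$adj_r2, feasible = m$feasible,
    stringsAsFactors = FALSE)))
  attr(models, "scenarios") <- scen
  models
}

#' Estimate a concentration from a calibration model
#'
#' Inverts the fitted curve at the observed response. Linear:
#' `x = (y - b0)/b1`. Quadratic: the real root of
#' `b2 x^2 + b1 x + (b0 - y) = 0` lying inside the fitted concentration
#' range (two in-range roots is an error; an out-of-range root triggers an
#' extrapolation warning and returns the root nearest the range).
#'
#' @param model A `calibration_model`, as returned in the list from
#'   [build_calibration()].
#' @param response Observed abundance.
#' @return Estimated concentration (attribute `"extrapolated"` set to TRUE
#'   when the response or the root lies outside the fitted range).
#' @export
estimate_concentration <- function(model, response) {
  if (!isTRUE(model$feasible) || is.null(model$coefficients))
    stop("model is not a feasible fitted calibration")
  b <- model$coefficients
  extrap <- response < model$y_range[1] || response > model$y_range[2]
  if (model$form == "linear") {
    if (b[2] == 0) stop("zero slope; concentration undefined")
    x <- (response - b[1]) / b[2]
  } else {
    disc <- b[2]^2 - 4 * b[3] * (b[1] - response)
    if (disc < 0) stop("no real root for this response")
    roots <- (-b[2] + c(-1, 1) * sqrt(disc)) / (2 * b[3])
    inside <- roots >= model$x_range[1] & roots <= model$x_range[2]
    if (sum(inside) == 2 && abs(roots[1] - roots[2]) > 1e-12)
      stop("both roots lie inside the fitted range (",
           paste(signif(roots, 6), collapse = ", "),
           "); concentration ambiguous")
    if (any(inside)) {
      x <- roots[inside][1]
    } else {
      dist <- pmin(abs(roots - model$x_range[1]), abs(roots - model$x_range[2]))
      x <- roots[which.min(dist)]
      extrap <- TRUE
    }
  }
  if (x < model$x_range[1] || x > model$x_range[2]) extrap <- TRUE
  if (extrap)
    warning("response outside the fitted calibration range; extrapolating")
  attr(x, "extrapolated") <- extrap
  x
}

#' Signed relative error of an estimated concentration
#'
#' `(estimated - nominal) / nominal * 100`.
#'
#' @param estimated Estimated concentration.
#' @param nominal Nominal (true) concentration, > 0.
#' @return Relative error in percent (signed).
#' @export
relative_error <- function(estimated, nominal) {
  if (any(nominal <= 0)) stop("nominal concentration must be > 0")
  (estimated - nominal) / nominal * 100
}
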
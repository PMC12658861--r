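#' Define a targeted compound
#'
#' @param name Compound name.
#' @param ms1_mz Expected precursor m/z (Da), > 0.
#' @param rt Expected retention time in seconds, or `NA` to let
#'   [detect_ms1()] assign it from the most intense matching MS1 centroid.
#' @param fragment_mz Numeric vector of true MS2 fragment m/z values
#'   (possibly empty).
#' @param mz_tol_ppm MS1 m/z tolerance in ppm (default 1000).
#' @param rt_tol Retention-time tolerance half-width in seconds (default 5).
#' @param fragment_tol Fragment m/z tolerance value (default 0.5).
#' @param fragment_tol_unit `"Da"` (default, suits integer-valued nominal
#'   fragment lists) or `"ppm"`.
#' @return An object of class `target_definition`.
#' @export
target_definition <- function(name, ms1_mz, rt = NA_real_,
                              fragment_mz = numeric(0),
                              mz_tol_ppm = 1000, rt_tol = 5,
                              fragment_tol = 0.5,
                              fragment_tol_unit = c("Da", "ppm")) {
  fragment_tol_unit <- match.arg(fragment_tol_unit)
  if (ms1_mz <= 0) stop("ms1_mz must be > 0")
  if (mz_tol_ppm <= 0 || rt_tol <= 0 || fragment_tol <= 0)
    stop("tolerances must be > 0")
  structure(list(name = as.character(name), ms1_mz = as.numeric(ms1_mz),
                 rt = as.numeric(rt), fragment_mz = as.numeric(fragment_mz),
                 mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
                 fragment_tol = fragment_tol,
                 fragment_tol_unit = fragment_tol_unit),
            class = "target_definition")
}

#' Read a target table
#'
#' TSV/CSV with columns `name`, `ms1_mz`, optional `rt` (seconds) and
#' optional `fragment_mz` (semicolon-separated list).
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param ... Passed to [target_definition()] (tolerances).
#' @return List of [target_definition()] objects.
#' @export
read_targets <- function(path, sep = "\t", ...) {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("name", "ms1_mz") %in% names(df)))
    stop("target table needs columns name, ms1_mz")
  lapply(seq_len(nrow(df)), function(i) {
    fr <- if ("fragment_mz" %in% names(df) && nzchar(df$fragment_mz[i]))
      as.numeric(strsplit(as.character(df$fragment_mz[i]), ";")[[1]])
    else numeric(0)
    rt <- if ("rt" %in% names(df)) df$rt[i] else NA_real_
    target_definition(df$name[i], df$ms1_mz[i], rt = rt, fragment_mz = fr, ...)
  })
}

#' Locate a target's MS1 peak
#'
#' Scans MS1 spectra for centroids within the target's ppm tolerance of its
#' expected m/z (restricted to `rt +/- rt_tol` when the target supplies an
#' RT) and returns the observed m/z and retention time of the most intense
#' match. Absence is data: no match returns `NA`s, not an error.
#'
#' @param run An [ms_run()].
#' @param target A [target_definition()].
#' @return List with `estimated_mz`, `rt`, `intensity` (all `NA` if no
#'   centroid falls inside the window).
#' @export
detect_ms1 <- function(run, target) {
  if (!any(run_levels(run) == 1L)) stop("run has no MS1 spectra")
  half <- target$ms1_mz * target$mz_tol_ppm * 1e-6
  best <- list(estimated_mz = NA_real_, rt = NA_real_, intensity = NA_real_)
  for (s in run$spectra) {
    if (s$ms_level != 1L) next
    if (!is.na(target$rt) && abs(s$rt - target$rt) > target$rt_tol) next
    hit <- which(abs(s$mz - target$ms1_mz) <= half)
    if (!length(hit)) next
    j <- hit[which.max(s$intensity[hit])]
    if (is.na(best$intensity) || s$intensity[j] > best$intensity) {
      best <- list(estimated_mz = s$mz[j], rt = s$rt, intensity = s$intensity[j])
    }
  }
  best
}

frag_half_width <- function(mz, tol, unit) {
  if (unit == "ppm") mz * tol * 1e-6 else tol
}

#' Match MS2 fragments for a target
#'
#' Searches MS2 spectra whose precursor lies within the target's MS1 ppm
#' tolerance and whose RT lies within `rt +/- rt_tol`. For each true
#' fragment m/z the most intense centroid within the fragment tolerance is
#' reported (ties broken toward lower m/z); undetected fragments are
#' returned as `NA`.
#'
#' @param run An [ms_run()].
#' @param target A [target_definition()].
#' @param rt Retention time (seconds), from the user or [detect_ms1()].
#' @return Data frame with one row per true fragment: `true_mz`,
#'   `estimated_mz`, `abundance` (`NA` when not detected).
#' @export
match_ms2 <- function(run, target, rt) {
  fr <- target$fragment_mz
  out <- data.frame(true_mz = fr, estimated_mz = NA_real_,
                    abundance = NA_real_)
  if (!length(fr) || is.na(rt)) return(out)
  prec_half <- target$ms1_mz * target$mz_tol_ppm * 1e-6
  for (s in run$spectra) {
    if (s$ms_level != 2L) next
    if (abs(s$rt - rt) > target$rt_tol) next
    if (abs(s$precursor_mz - target$ms1_mz) > prec_half) next
    for (i in seq_along(fr)) {
      half <- frag_half_width(fr[i], target$fragment_tol,
                              target$fragment_tol_unit)
      hit <- which(abs(s$mz - fr[i]) <= half)
      if (!length(hit)) next
      j <- hit[which.max(s$intensity[hit])]  # which.max: lower m/z wins ties
      if (is.na(out$abundance[i]) || s$intensity[j] > out$abundance[i]) {
        out$estimated_mz[i] <- s$mz[j]
        out$abundance[i] <- s$intensity[j]
      }
    }
  }
  out
}

#' Integrate peak abundance over an RT window
#'
#' Accumulates extracted-ion-chromatogram intensity over
#' `[rt - rt_window, rt + rt_window]`.
#'
#' @param run An [ms_run()].
#' @param mz Query m/z.
#' @param rt Window centre (seconds).
#' @param mz_tol Tolerance value (default 1000).
#' @param rt_window Half-width in seconds (default 5).
#' @param mz_tol_unit `"ppm"` (default) or `"Da"`.
#' @return Summed intensity (0 with a warning for an empty window).
#' @export
integrate_abundance <- function(run, mz, rt, mz_tol = 1000, rt_window = 5,
                                mz_tol_unit = c("ppm", "Da")) {
  mz_tol_unit <- match.arg(mz_tol_unit)
  if (mz_tol <= 0 || rt_window <= 0) stop("windows must be positive")
  tol_ppm <- if (mz_tol_unit == "ppm") mz_tol else mz_tol / mz * 1e6
  x <- extract_xic(run, mz, tol_ppm, rt_range = c(rt - rt_window, rt + rt_window))
  if (nrow(x) == 0L) {
    warning("no MS1 spectra in RT window; abundance 0")
    return(0)
  }
  sum(x$intensity)
}

#' Signal-to-noise ratio of an intensity series
#'
#' Mean divided by (sample, n-1 denominator) standard deviation.
#'
#' @param values Numeric vector of intensities or abundances (NA dropped),
#'   at least 2 non-missing values.
#' @return `mean/sd`; `Inf` with a warning when the sd is zero.
#' @export
signal_to_noise <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("signal_to_noise needs at least 2 values")
  s <- sd(values)
  if (s == 0) {
    warning("zero standard deviation; S/N undefined, returning Inf")
    return(Inf)
  }
  mean(values) / s
}

#' Relative fragment abundance
#'
#' Scales fragment intensities to percent of the base (most intense) peak;
#' `NA` propagates. With at least one detected fragment the base peak is
#' exactly 100.
#'
#' @param fragment_intensities Numeric vector (NA allowed).
#' @return Percentages in `[0, 100]` (all `NA` if no fragment detected).
#' @export
relative_abundance <- function(fragment_intensities) {
  if (all(is.na(fragment_intensities)))
    return(rep(NA_real_, length(fragment_intensities)))
  fragment_intensities * 100 / max(fragment_intensities, na.rm = TRUE)
}

#' Analyze a batch of targets
#'
#' Runs peak detection, MS2 fragment matching, abundance integration and
#' quality summaries for each target. Per-target misses yield `NA` rows;
#' the batch never aborts on a single absent compound. The per-run S/N
#' reported here is computed over the XIC points inside the RT window
#' (`sn_mode = "xic"`); feature-level S/N across samples is available from
#' [peak_metrics()].
#'
#' @param run An [ms_run()].
#' @param targets List of [target_definition()] objects.
#' @return List with elements `ms1` (one row per target: `name`, `true_mz`,
#'   `estimated_mz`, `rt`, `abundance`, `sn`), `ms2` (one row per fragment:
#'   `name`, `true_mz`, `estimated_mz`, `abundance`,
#'   `relative_abundance`), and `spectra` (per-target XIC data frames).
#' @export
analyze_targets <- function(run, targets) {
  ms1 <- data.frame(name = character(0), true_mz = numeric(0),
                    estimated_mz = numeric(0), rt = numeric(0),
                    abundance = numeric(0), sn = numeric(0))
  ms2 <- data.frame(name = character(0), true_mz = numeric(0),
                    estimated_mz = numeric(0), abundance = numeric(0),
                    relative_abundance = numeric(0))
  spectra <- list()
  for (tg in targets) {
    det <- detect_ms1(run, tg)
    if (is.na(det$estimated_mz)) {
      ms1 <- rbind(ms1, data.frame(name = tg$name, true_mz = tg$ms1_mz,
                                   estimated_mz = NA_real_, rt = NA_real_,
                                   abundance = NA_real_, sn = NA_real_))
      if (length(tg$fragment_mz))
        ms2 <- rbind(ms2, data.frame(name = tg$name, true_mz = tg$fragment_mz,
                                     estimated_mz = NA_real_,
                                     abundance = NA_real_,
                                     relative_abundance = NA_real_))
      next
    }
    xic <- extract_xic(run, tg$ms1_mz, tg$mz_tol_ppm,
                       rt_range = c(det$rt - tg$rt_tol, det$rt + tg$rt_tol))
    abundance <- sum(xic$intensity)
    sn <- if (nrow(xic) >= 2 && sd(xic$intensity) > 0)
      mean(xic$intensity) / sd(xic$intensity) else NA_real_
    ms1 <- rbind(ms1, data.frame(name = tg$name, true_mz = tg$ms1_mz,
                                 estimated_mz = det$estimated_mz, rt = det$rt,
                                 abundance = abundance, sn = sn))
    spectra[[tg$name]] <- xic
    if (length(tg$fragment_mz)) {
      fm <- match_ms2(run, tg, rt = if (is.na(tg$rt)) det$rt else tg$rt)
      fm$relative_abundance <- relative_abundance(fm$abundance)
      ms2 <- rbind(ms2, cbind(name = tg$name, fm))
    }
  }
  rownames(ms1) <- rownames(ms2) <- NULL
  list(ms1 = ms1, ms2 = ms2, spectra = spectra)
}
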
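#' Construct a single mass spectrum
#'
#' A centroided spectrum: an ordered m/z array with matching intensities,
#' an MS level (1 for survey scans, 2 for product-ion scans) and a retention
#' time in seconds. MS2 spectra must carry the precursor m/z they were
#' acquired from.
#'
#' @param mz Numeric vector of centroid m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param ms_level Integer, 1 or 2.
#' @param rt Retention time in seconds.
#' @param precursor_mz Precursor m/z (required iff `ms_level == 2`).
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(mz, intensity, ms_level = 1L, rt = 0,
                        precursor_mz = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  ms_level <- as.integer(ms_level)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (ms_level == 2L && (is.null(precursor_mz) || is.na(precursor_mz)))
    stop("MS2 spectra require a precursor_mz")
  if (ms_level == 1L) precursor_mz <- NA_real_
  structure(
    list(mz = mz, intensity = intensity, ms_level = ms_level,
         rt = as.numeric(rt), precursor_mz = as.numeric(precursor_mz)),
    class = "ms_spectrum")
}

#' Construct an LC-MS run
#'
#' @param spectra List of [ms_spectrum()] objects ordered by retention time.
#' @param run_id Character run identifier.
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(spectra = list(), run_id = "run") {
  if (!all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
    stop("all elements of spectra must be ms_spectrum objects")
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (length(rts) > 1 && any(diff(rts) < 0))
    stop("spectra must be ordered by non-decreasing retention time")
  structure(list(spectra = spectra, run_id = as.character(run_id)),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run '%s': %d spectra (%d MS1, %d MS2)>\n",
              x$run_id, length(lv), sum(lv == 1L), sum(lv == 2L)))
  invisible(x)
}

#' @export
length.ms_run <- function(x) length(x$spectra)

run_rts <- function(run) vapply(run$spectra, `[[`, numeric(1), "rt")
run_levels <- function(run) vapply(run$spectra, `[[`, integer(1), "ms_level")

#' Read a centroided mzML file
#'
#' Reads all MS1 and MS2 spectra from a PSI-standard mzML file. Retention
#' times are stored in seconds and MS2 spectra keep their precursor m/z.
#' Profile-mode spectra are rejected rather than silently centroided.
#'
#' @param path Path to an mzML file.
#' @return An [ms_run()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L)
    return(ms_run(list(), run_id = basename(path)))
  if (!is.null(hd$centroided) && any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectrum at scan index ",
         which(!is.na(hd$centroided) & !hd$centroided)[1],
         "; only centroided data are supported")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    lvl <- hd$msLevel[i]
    if (!lvl %in% c(1L, 2L))
      stop("unsupported MS level ", lvl, " at scan index ", i)
    prec <- hd$precursorMZ[i]
    if (lvl == 2L && (is.na(prec) || prec <= 0))
      stop("MS2 spectrum at scan index ", i, " lacks a precursor m/z")
    m <- pk[[i]]
    o <- order(m[, 1])
    spectra[[i]] <- ms_spectrum(m[o, 1], m[o, 2], ms_level = lvl,
                                rt = hd$retentionTime[i],
                                precursor_mz = if (lvl == 2L) prec else NULL)
  }
  ord <- order(hd$retentionTime)
  ms_run(spectra[ord], run_id = basename(path))
}

#' Write a run to mzML
#'
#' @param run An [ms_run()].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (!inherits(run, "ms_run")) stop("run must be an ms_run")
  n <- length(run$spectra)
  if (n == 0L) {
    hdr <- empty_mzr_header(0L)
    mzR::writeMSData(list(), file = path, header = hdr)
    return(invisible(path))
  }
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  hdr <- empty_mzr_header(n)
  prev_ms1 <- 0L
  for (i in seq_len(n)) {
    s <- run$spectra[[i]]
    hdr$msLevel[i] <- s$ms_level
    hdr$retentionTime[i] <- s$rt
    hdr$peaksCount[i] <- length(s$mz)
    hdr$totIonCurrent[i] <- sum(s$intensity)
    if (length(s$mz)) {
      bp <- which.max(s$intensity)
      hdr$basePeakMZ[i] <- s$mz[bp]
      hdr$basePeakIntensity[i] <- s$intensity[bp]
      hdr$lowMZ[i] <- min(s$mz)
      hdr$highMZ[i] <- max(s$mz)
    }
    if (s$ms_level == 1L) prev_ms1 <- i
    if (s$ms_level == 2L) {
      hdr$precursorMZ[i] <- s$precursor_mz
      hdr$precursorCharge[i] <- 1L
      hdr$precursorScanNum[i] <- prev_ms1
      hdr$isolationWindowTargetMZ[i] <- s$precursor_mz
      hdr$isolationWindowLowerOffset[i] <- 1
      hdr$isolationWindowUpperOffset[i] <- 1
    }
  }
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

# Fully-populated mzR header skeleton (all columns writeMSData expects).
empty_mzr_header <- function(n) {
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n),
    peaksCount = rep(0L, n), totIonCurrent = rep(0, n),
    retentionTime = rep(0, n), basePeakMZ = rep(0, n),
    basePeakIntensity = rep(0, n), collisionEnergy = rep(0, n),
    ionisationEnergy = rep(0, n), lowMZ = rep(0, n), highMZ = rep(0, n),
    precursorScanNum = rep(0L, n), precursorMZ = rep(0, n),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = if (n) paste0("scan=", seq_len(n)) else character(0),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic targeted LC-MS/MS run
#'
#' Emulates a mixture injection of known compounds: each target produces a
#' Gaussian chromatographic elution profile on the MS1 retention-time grid
#' plus, at the apex scan, one MS2 spectrum carrying the stated fragments.
#' Gaussian baseline noise (standard deviation `noise_sd`, truncated at
#' zero) is added to every generated centroid. Deterministic given `seed`.
#'
#' @param targets List of targets; each a list with `mz`, `rt_apex` (s),
#'   `height` (apex intensity) and optionally `fragments`, a data frame with
#'   columns `mz` and `intensity`.
#' @param noise_sd Baseline noise standard deviation (intensity counts).
#' @param rt_grid Numeric vector of MS1 scan retention times (seconds).
#' @param peak_width Chromatographic Gaussian sigma in seconds (default 3).
#' @param seed Integer seed; `NULL` leaves the RNG untouched.
#' @param run_id Run identifier.
#' @return An [ms_run()].
#' @export
synthesize_run <- function(targets, noise_sd = 0, rt_grid,
                           peak_width = 3, seed = NULL, run_id = "synthetic") {
  if (length(rt_grid) == 0L) stop("rt_grid must be non-empty")
  rt_grid <- sort(as.numeric(rt_grid))
  heights <- vapply(targets, `[[`, numeric(1), "height")
  if (any(heights <= 0)) stop("target heights must be > 0")
  with_seed(seed, {
    spectra <- list()
    for (rt in rt_grid) {
      mzv <- numeric(0); inv <- numeric(0)
      for (tg in targets) {
        val <- tg$height * exp(-(rt - tg$rt_apex)^2 / (2 * peak_width^2))
        if (noise_sd > 0) val <- max(0, val + rnorm(1, 0, noise_sd))
        if (val > 0) { mzv <- c(mzv, tg$mz); inv <- c(inv, val) }
      }
      o <- order(mzv)
      spectra[[length(spectra) + 1L]] <-
        ms_spectrum(mzv[o], inv[o], ms_level = 1L, rt = rt)
      for (tg in targets) {
        fr <- tg$fragments
        if (is.null(fr) || !nrow(fr)) next
        apex_scan <- rt_grid[which.min(abs(rt_grid - tg$rt_apex))]
        if (!isTRUE(all.equal(rt, apex_scan))) next
        fi <- fr$intensity
        if (noise_sd > 0) fi <- pmax(0, fi + rnorm(length(fi), 0, noise_sd))
        keep <- fi > 0
        if (!any(keep)) next
        o <- order(fr$mz[keep])
        spectra[[length(spectra) + 1L]] <-
          ms_spectrum(fr$mz[keep][o], fi[keep][o], ms_level = 2L, rt = rt,
                      precursor_mz = tg$mz)
      }
    }
    ms_run(spectra, run_id = run_id)
  })
}

#' Extract an ion chromatogram
#'
#' For each MS1 spectrum inside `rt_range`, sums the intensities of all
#' centroids whose m/z lies within `tol_ppm` parts-per-million of the query
#' m/z (tolerance relative to the query). Matching centroids within one scan
#' are summed, not maxed.
#'
#' @param run An [ms_run()].
#' @param mz Query m/z (Da).
#' @param tol_ppm Tolerance in ppm of the query m/z; must be > 0.
#' @param rt_range Optional length-2 numeric `c(lo, hi)` in seconds;
#'   `NULL` uses the whole run.
#' @return Data frame with columns `rt` and `intensity` (one row per MS1
#'   spectrum in range; zero rows for an empty window).
#' @export
extract_xic <- function(run, mz, tol_ppm = 1000, rt_range = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (!is.null(rt_range)) {
    if (length(rt_range) != 2 || rt_range[1] > rt_range[2])
      stop("rt_range must be c(lo, hi) with lo <= hi")
  }
  half <- mz * tol_ppm * 1e-6
  rt <- numeric(0); intensity <- numeric(0)
  for (s in run$spectra) {
    if (s$ms_level != 1L) next
    if (!is.null(rt_range) && (s$rt < rt_range[1] || s$rt > rt_range[2])) next
    hit <- abs(s$mz - mz) <= half
    rt <- c(rt, s$rt)
    intensity <- c(intensity, sum(s$intensity[hit]))
  }
  data.frame(rt = rt, intensity = intensity)
}
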
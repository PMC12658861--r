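# Monoisotopic (most-abundant isotope) atomic masses, Da (IUPAC/AME).
MONOISOTOPIC_MASSES <- c(
  H = 1.0078250319, D = 2.0141017781, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, F = 18.9984031627, Na = 22.9897692820,
  Mg = 23.9850416970, Al = 26.9815385300, Si = 27.9769265350,
  P = 30.9737619984, S = 31.9720711744, Cl = 34.9688526900,
  K = 38.9637064864, Ca = 39.9625909860, Cr = 51.9405062300,
  Mn = 54.9380439100, Fe = 55.9349363300, Ni = 57.9353424200,
  Cu = 62.9295977200, Zn = 63.9291420100, As = 74.9215945700,
  Se = 79.9165218000, Br = 78.9183376000, I = 126.9044719000,
  B = 11.0093053600, Li = 7.0160034370)

# Mass of a proton (an electron lighter than the hydrogen atom); the
# convention behind [M+H]+ adduct m/z values.
PROTON_MASS <- 1.007276
ELECTRON_MASS <- 0.00054858

#' Parse a molecular formula
#'
#' Accepts Hill-notation-like strings, with or without subscript markers
#' (underscores are stripped), e.g. `"C17H19NO3"` or `"C_17_H_19_NO_3_"`.
#' Implicit counts are 1; repeated element symbols accumulate.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts (class `ms_formula`).
#' @export
parse_formula <- function(text) {
  clean <- gsub("[_ ]", "", text)
  if (!nzchar(clean)) return(structure(integer(0), class = "ms_formula"))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  pieces <- regmatches(clean, gregexpr("([A-Z][a-z]?)([0-9]*)", clean))[[1]]
  if (sum(attr(m, "match.length")) != nchar(clean))
    stop("cannot parse formula: ", text)
  counts <- integer(0)
  for (pc in pieces) {
    el <- gsub("[0-9]", "", pc)
    ct <- gsub("[^0-9]", "", pc)
    ct <- if (nzchar(ct)) as.integer(ct) else 1L
    if (!el %in% names(MONOISOTOPIC_MASSES))
      stop("unknown element symbol: ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + ct
  }
  structure(counts, class = "ms_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum of counts times most-abundant-isotope masses.
#'
#' @param f An `ms_formula` from [parse_formula()] (a formula string is
#'   also accepted).
#' @return Neutral monoisotopic mass in Da (0 for an empty formula).
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (!length(f)) return(0)
  sum(unclass(f) * MONOISOTOPIC_MASSES[names(f)])
}

#' Shipped adduct registry
#'
#' Common electrospray adducts: `(multiplicity * M + mass_shift) /
#' |charge|`. Positive-mode shifts use the proton mass convention
#' (+1.007276 Da for M+H), metal adducts subtract one electron mass.
#'
#' @return Data frame with columns `name`, `multiplicity`, `mass_shift`,
#'   `charge`.
#' @export
adduct_registry <- function() {
  data.frame(
    name = c("M+H", "M+Na", "M+K", "M+NH4", "2M+H", "M-H", "M+Cl", "M"),
    multiplicity = c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L),
    mass_shift = c(PROTON_MASS,
                   MONOISOTOPIC_MASSES[["Na"]] - ELECTRON_MASS,
                   MONOISOTOPIC_MASSES[["K"]] - ELECTRON_MASS,
                   MONOISOTOPIC_MASSES[["N"]] + 4 * MONOISOTOPIC_MASSES[["H"]] -
                     ELECTRON_MASS,
                   PROTON_MASS,
                   -PROTON_MASS,
                   MONOISOTOPIC_MASSES[["Cl"]] + ELECTRON_MASS,
                   0),
    charge = c(1L, 1L, 1L, 1L, 1L, -1L, -1L, 1L),
    stringsAsFactors = FALSE)
}

#' Adduct m/z from a neutral mass
#'
#' @param M Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct name from [adduct_registry()], or a one-row data
#'   frame with `multiplicity`, `mass_shift`, `charge`.
#' @return m/z of the adduct ion (the neutral `"M"` pseudo-adduct returns
#'   `M` itself for neutral-mass queries).
#' @export
adduct_mz <- function(M, adduct = "M+H") {
  if (any(M <= 0)) stop("M must be > 0")
  if (is.character(adduct)) {
    reg <- adduct_registry()
    row <- reg[reg$name == adduct, ]
    if (!nrow(row)) stop("unknown adduct: ", adduct)
  } else row <- as.data.frame(adduct)
  if (row$charge == 0) stop("adduct charge must be nonzero")
  (row$multiplicity * M + row$mass_shift) / abs(row$charge)
}

#' Relative mass difference in ppm
#'
#' `|observed - reference| / reference * 1e6`; the reference (adduct) m/z
#' is the denominator.
#'
#' @param observed,reference m/z values; `reference > 0`.
#' @return Absolute delta in ppm.
#' @export
ppm_delta <- function(observed, reference) {
  if (any(reference <= 0)) stop("reference m/z must be > 0")
  abs(observed - reference) / reference * 1e6
}

#' Read a compound-database snapshot
#'
#' TSV with columns `db_name`, `db_id`, optional `xref_id`, `name`,
#' `formula`, optional `monoisotopic_mass`. A missing mass is computed from
#' the formula; a supplied mass must agree with the formula within 1 ppm.
#'
#' @param path Snapshot file path.
#' @return Data frame of compound records.
#' @export
read_compound_db <- function(path) {
  db <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("db_name", "db_id", "name", "formula")
  if (!all(need %in% names(db)))
    stop("compound DB needs columns ", paste(need, collapse = ", "))
  if (!"xref_id" %in% names(db)) db$xref_id <- NA_character_
  calc <- vapply(db$formula, monoisotopic_mass, numeric(1))
  if (!"monoisotopic_mass" %in% names(db)) {
    db$monoisotopic_mass <- calc
  } else {
    miss <- is.na(db$monoisotopic_mass)
    db$monoisotopic_mass[miss] <- calc[miss]
    bad <- which(!miss & abs(db$monoisotopic_mass - calc) / calc * 1e6 > 1)
    if (length(bad))
      stop("monoisotopic_mass inconsistent with formula for: ",
           paste(db$db_id[bad], collapse = ", "))
  }
  db
}

#' Batch accurate-mass database matching
#'
#' For each query m/z (or neutral mass) and each mode-compatible adduct,
#' returns every database record whose adduct m/z lies within the
#' tolerance, sorted by delta ascending (ties by `db_id`). Queries with no
#' hit yield a single NA row, so absences stay visible in the output.
#'
#' @param queries Numeric vector of target m/z values (named entries label
#'   the output), or a data frame with columns `name` and `mz`.
#' @param db Compound records from [read_compound_db()] (or an equivalent
#'   data frame).
#' @param adducts Character vector of adduct names (default `"M+H"`).
#' @param tol Tolerance value (default 3).
#' @param tol_unit `"ppm"` (default) or `"Da"`.
#' @param mode `"positive"`, `"negative"` or `"neutral"`: restricts the
#'   adduct list to compatible charges.
#' @return Data frame with columns `query`, `target_mz`, `adduct`,
#'   `db_name`, `db_id`, `xref_id`, `name`, `formula`, `adduct_mz`,
#'   `delta`, `delta_unit`.
#' @export
match_database <- function(queries, db, adducts = "M+H", tol = 3,
                           tol_unit = c("ppm", "Da"),
                           mode = c("positive", "negative", "neutral")) {
  tol_unit <- match.arg(tol_unit)
  mode <- match.arg(mode)
  if (is.null(db) || !nrow(db)) stop("compound database is empty")
  if (tol <= 0) stop("tolerance must be > 0")
  if (is.data.frame(queries)) {
    qnames <- as.character(queries$name); qmz <- as.numeric(queries$mz)
  } else {
    qmz <- as.numeric(queries)
    qnames <- if (!is.null(names(queries))) names(queries)
              else paste0("Q", seq_along(qmz))
  }
  reg <- adduct_registry()
  reg <- reg[reg$name %in% adducts, , drop = FALSE]
  reg <- switch(mode,
    positive = reg[reg$charge > 0 & reg$name != "M", , drop = FALSE],
    negative = reg[reg$charge < 0, , drop = FALSE],
    neutral = reg[reg$name == "M", , drop = FALSE])
  if (!nrow(reg)) stop("no adduct compatible with mode ", mode)
  masses <- if ("monoisotopic_mass" %in% names(db)) db$monoisotopic_mass
            else vapply(db$formula, monoisotopic_mass, numeric(1))
  na_row <- function(qn, qz) data.frame(
    query = qn, target_mz = qz, adduct = NA_character_,
    db_name = NA_character_, db_id = NA_character_, xref_id = NA_character_,
    name = NA_character_, formula = NA_character_, adduct_mz = NA_real_,
    delta = NA_real_, delta_unit = tol_unit, stringsAsFactors = FALSE)
  out <- list()
  for (qi in seq_along(qmz)) {
    hits <- list()
    for (ai in seq_len(nrow(reg))) {
      amz <- (reg$multiplicity[ai] * masses + reg$mass_shift[ai]) /
        abs(reg$charge[ai])
      delta <- if (tol_unit == "ppm") abs(qmz[qi] - amz) / amz * 1e6
               else abs(qmz[qi] - amz)
      sel <- which(delta <= tol)
      if (length(sel))
        hits[[length(hits) + 1L]] <- data.frame(
          query = qnames[qi], target_mz = qmz[qi], adduct = reg$name[ai],
          db_name = db$db_name[sel], db_id = db$db_id[sel],
          xref_id = db$xref_id[sel], name = db$name[sel],
          formula = db$formula[sel], adduct_mz = amz[sel],
          delta = delta[sel], delta_unit = tol_unit,
          stringsAsFactors = FALSE)
    }
    if (!length(hits)) { out[[length(out) + 1L]] <- na_row(qnames[qi], qmz[qi]); next }
    h <- do.call(rbind, hits)
    h <- h[order(h$delta, h$db_id), , drop = FALSE]
    out[[length(out) + 1L]] <- h
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
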
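# Formula/adduct-based annotation: monoisotopic masses from molecular
# formulas, electron-corrected adduct m/z, and ppm-tolerance peak matching.

# most-abundant-isotope masses (IUPAC/CODATA, Da)
ELEMENT_MASSES <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.96885268)

ELECTRON_MASS <- 0.00054857990946

# signed, electron-corrected adduct deltas (mass of the charged species
# minus the neutral monoisotopic mass)
ADDUCT_DELTAS <- c(
  "[M+H]+"  = 1.0078250319 - 0.00054857990946,
  "[M+Na]+" = 22.98976928 - 0.00054857990946,
  "[M+K]+"  = 38.9637064864 - 0.00054857990946,
  "[M-H]-"  = -(1.0078250319 - 0.00054857990946),
  "[M+Cl]-" = 34.96885268 + 0.00054857990946)

ADDUCT_POLARITY <- c(
  "[M+H]+" = "positive", "[M+Na]+" = "positive", "[M+K]+" = "positive",
  "[M-H]-" = "negative", "[M+Cl]-" = "negative")

normalize_adduct <- function(label) {
  # tolerate the unicode minus sign used in print
  gsub("−", "-", label)
}

#' Parse a molecular formula
#'
#' Hill-style element counts, e.g. `"C42H82NO8P"`. Supported elements:
#' C, H, N, O, P, S, Na, K, Cl.
#'
#' @param formula Formula string (or an already-named count vector).
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(formula)) {
      abort(sprintf("cannot parse formula '%s'", formula))
    }
    el <- sub("[0-9]*$", "", toks)
    nc <- sub("^[A-Z][a-z]?", "", toks)
    counts <- as.numeric(ifelse(nc == "", "1", nc))
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
  }
  bad <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(bad)) {
    abort(sprintf("unsupported element(s) in formula: %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(counts <= 0 | counts != round(counts))) {
    abort("element counts must be positive integers")
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses.
#'
#' @param formula Formula string or named count vector (see
#'   [parse_formula()]).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * ELEMENT_MASSES[names(counts)])
}

#' Theoretical adduct m/z
#'
#' Neutral monoisotopic mass plus the electron-corrected adduct delta.
#' Supported adducts: `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M-H]-`, `[M+Cl]-`.
#'
#' @param formula Formula string or named count vector.
#' @param adduct Adduct label.
#' @return m/z of the charged species in Da.
#' @export
adduct_mz <- function(formula, adduct) {
  adduct <- normalize_adduct(adduct)
  if (!adduct %in% names(ADDUCT_DELTAS)) {
    abort(sprintf("unknown adduct '%s' (supported: %s)", adduct,
                  paste(names(ADDUCT_DELTAS), collapse = ", ")))
  }
  monoisotopic_mass(formula) + unname(ADDUCT_DELTAS[adduct])
}

#' Read a compound reference table
#'
#' Tab-separated text with header `name`, `formula`, `class`, `adducts`
#' (comma-separated adduct labels); extra columns pass through.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_compound_table <- function(path) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      colClasses = "character",
                                      check.names = FALSE))
  need <- c("name", "formula", "adducts")
  if (!all(need %in% names(tab))) {
    abort(sprintf("compound table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  tab
}

#' Match observed peaks against a compound table
#'
#' Every (peak, compound, adduct) combination whose signed mass error
#' `1e6 * (obs - theo) / theo` lies within the tolerance is reported, sorted
#' by absolute ppm error; peaks with more than one hit are flagged
#' ambiguous. With `tol_da` set, a Da window is used instead of ppm (the
#' TOF-mode convention, where bins are far wider than the ppm accuracy of
#' FT-ICR data).
#'
#' @param peaks Numeric vector of observed m/z values.
#' @param table Compound tibble from [read_compound_table()] (columns
#'   `name`, `formula`, `adducts`).
#' @param adducts Optional character vector restricting the adducts tried;
#'   default: each compound's own `adducts` column.
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param tol_da Optional absolute tolerance in Da; overrides `tol_ppm`.
#' @param polarity Optional `"positive"`/`"negative"` filter on adducts.
#' @return A tibble: `observed_mz`, `name`, `adduct`, `theoretical_mz`,
#'   `ppm_error`, `ambiguous`.
#' @export
match_peaks <- function(peaks, table, adducts = NULL, tol_ppm = 5,
                        tol_da = NULL, polarity = NULL) {
  stopifnot(is.null(tol_da) || tol_da > 0, tol_ppm > 0)
  empty <- tibble::tibble(observed_mz = numeric(), name = character(),
                          adduct = character(), theoretical_mz = numeric(),
                          ppm_error = numeric(), ambiguous = logical())
  if (!length(peaks)) return(empty)

  theo <- dplyr::bind_rows(lapply(seq_len(nrow(table)), function(i) {
    adds <- if (!is.null(adducts)) adducts else
      trimws(strsplit(table$adducts[i], ",")[[1]])
    adds <- normalize_adduct(adds)
    if (!is.null(polarity)) {
      adds <- adds[ADDUCT_POLARITY[adds] == polarity]
    }
    if (!length(adds)) return(NULL)
    tibble::tibble(name = table$name[i], adduct = adds,
                   theoretical_mz = vapply(adds, function(a)
                     adduct_mz(table$formula[i], a), numeric(1)))
  }))
  if (is.null(theo) || !nrow(theo)) return(empty)

  hits <- dplyr::bind_rows(lapply(peaks, function(obs) {
    ppm <- 1e6 * (obs - theo$theoretical_mz) / theo$theoretical_mz
    ok <- if (!is.null(tol_da)) {
      abs(obs - theo$theoretical_mz) <= tol_da
    } else {
      abs(ppm) <= tol_ppm
    }
    if (!any(ok)) return(NULL)
    tibble::tibble(observed_mz = obs, name = theo$name[ok],
                   adduct = theo$adduct[ok],
                   theoretical_mz = theo$theoretical_mz[ok],
                   ppm_error = ppm[ok], ambiguous = sum(ok) > 1)
  }))
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits[order(abs(hits$ppm_error)), ]
}
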
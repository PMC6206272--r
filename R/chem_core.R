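#' Conventional atomic weights
#'
#' Average atomic weights (unified atomic mass units, u) following the IUPAC
#' conventional values. These are the defaults used throughout the package;
#' every function taking a `weights` argument accepts an alternative table,
#' so other conventions can be injected for sensitivity checks.
#'
#' @return Named numeric vector of atomic weights in u.
#' @export
#' @examples
#' atomic_weights()[["C"]]
atomic_weights <- function() {
  c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06, P = 30.974)
}

#' Parse a molecular formula string
#'
#' Parses formulas written in the usual element-count grammar ("C20H26O4",
#' "CH4") into a named integer vector of element counts. An omitted count
#' means 1. Parsing is strict: the whole string must be consumed by
#' element-count tokens, and the result must round-trip through
#' [format_formula()].
#'
#' @param text Formula string, e.g. `"C20H26O4"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C20H26O4")
#' parse_formula("CH4")
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U")

parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty molecular formula")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(
      substr(text, pos, n),
      regexpr("^([A-Z][a-z]?)([0-9]*)", substr(text, pos, n))
    )
    if (length(m) == 0L || !nzchar(m)) {
      stop(sprintf("malformed formula '%s': cannot parse at position %d ('%s')",
                   text, pos, substr(text, pos, pos)))
    }
    sym <- sub("[0-9]*$", "", m)
    if (!sym %in% ELEMENT_SYMBOLS) {
      stop(sprintf("malformed formula '%s': unknown element '%s' at position %d",
                   text, sym, pos))
    }
    num <- sub("^[A-Za-z]+", "", m)
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    if (cnt < 1L) {
      stop(sprintf("malformed formula '%s': zero count for element '%s' at position %d",
                   text, sym, pos))
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m)
  }
  counts
}

#' Format element counts as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' a count of 1 is omitted. Inverse of [parse_formula()] up to token order.
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(counts) {
  stopifnot(length(counts) >= 1L, !is.null(names(counts)), all(counts >= 1))
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (counts[[s]] == 1L) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

#' Average molecular weight of a formula
#'
#' @param formula A formula string or a named element-count vector as
#'   returned by [parse_formula()].
#' @param weights Atomic weight table; defaults to [atomic_weights()].
#' @return Molecular weight in u.
#' @export
#' @examples
#' round(average_molecular_weight("C20H26O4"), 2) # 330.42
average_molecular_weight <- function(formula, weights = atomic_weights()) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  stopifnot(length(counts) >= 1L, !is.null(names(counts)))
  unknown <- setdiff(names(counts), names(weights))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  sum(as.numeric(counts) * weights[names(counts)])
}

co2_mass <- function(weights = atomic_weights()) {
  average_molecular_weight(c(C = 1L, O = 2L), weights)
}

#' Registry of the twelve quantified cannabinoids
#'
#' Returns the analyte registry: the quantified LC-MS panel of twelve
#' cannabinoids with their lineage, alkyl side-chain class (propyl C3 vs
#' pentyl C5), ring class (dicyclic CBD-type vs tricyclic THC-type, plus
#' the CBG-type precursors and CBN/CBC), acid/neutral form, molecular
#' formula, the acid partner of each neutral, and the SIM target m/z
#' ([M+H]+, average mass). The registry ships as a plain CSV under
#' `inst/extdata` so it is auditable; a different file may be supplied to
#' override it.
#'
#' @param path Optional path to an alternative registry CSV with the same
#'   columns.
#' @return A data.frame with one row per analyte.
#' @export
#' @examples
#' analyte_registry()$code
analyte_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "analytes.csv", package = "chemovar", mustWork = TRUE)
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("code", "lineage", "alkyl_class", "ring_class", "form",
                "formula", "acid_partner", "sim_mz")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0L) {
    stop("registry missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$code)) stop("duplicate analyte codes in registry")
  rownames(reg) <- reg$code
  reg
}

#' The eight fraction analytes
#'
#' The four acids (THCA, CBDA, THCVA, CBDVA) and their neutral
#' decarboxylation products that together define the total cannabinoid
#' fraction and the four chemotype fraction statistics.
#'
#' @return Character vector of analyte codes.
#' @export
fraction_analytes <- function() {
  c("THCA", "THC", "CBDA", "CBD", "THCVA", "THCV", "CBDVA", "CBDV")
}

#' Acid conversion factor for a neutral cannabinoid
#'
#' Ratio of the molecular weight of a neutral cannabinoid's acid partner to
#' its own, used to express neutral concentrations as acid equivalents
#' (the acid carries an extra CO2 lost on decarboxylation). Returned at
#' full precision; truncated to 4 decimals the C3 factor is 1.1536 and the
#' C5 factor is 1.1399 (see [conversion_factors()]).
#'
#' @param code Analyte code of a neutral cannabinoid with an acid partner.
#' @param registry Analyte registry, see [analyte_registry()].
#' @param weights Atomic weight table.
#' @return Dimensionless ratio > 1.
#' @export
#' @examples
#' acid_conversion_factor("THCV") # ~1.15365
acid_conversion_factor <- function(code, registry = analyte_registry(),
                                   weights = atomic_weights()) {
  if (!code %in% registry$code) stop(sprintf("unknown analyte '%s'", code))
  row <- registry[code, ]
  if (!identical(row$form, "neutral")) {
    stop(sprintf("'%s' is not a neutral cannabinoid", code))
  }
  if (is.na(row$acid_partner)) {
    stop(sprintf("'%s' has no acid partner in the registry", code))
  }
  acid <- registry[row$acid_partner, ]
  average_molecular_weight(acid$formula, weights) /
    average_molecular_weight(row$formula, weights)
}

#' C3 and C5 acid conversion factors
#'
#' Convenience accessor for the two molecular-weight conversion factors
#' used in the fraction formulas. With `printed = TRUE` the 4-decimal
#' truncated constants (1.1536, 1.1399) are returned instead of the
#' full-precision ratios; internal computation defaults to full precision
#' and the truncated constants exist for bit-compatible regression against
#' published arithmetic.
#'
#' @param printed Use the truncated printed constants.
#' @param registry,weights See [acid_conversion_factor()].
#' @return Named numeric vector `c(C3 = ..., C5 = ...)`.
#' @export
conversion_factors <- function(printed = FALSE, registry = analyte_registry(),
                               weights = atomic_weights()) {
  if (printed) return(c(C3 = 1.1536, C5 = 1.1399))
  c(C3 = acid_conversion_factor("THCV", registry, weights),
    C5 = acid_conversion_factor("THC", registry, weights))
}

#' Truncate (not round) to a number of decimal places
#'
#' Used only to check full-precision conversion factors against their
#' truncated printed forms.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept.
#' @return Truncated values.
#' @export
truncate_decimal <- function(x, digits = 4L) {
  trunc(x * 10^digits) / 10^digits
}
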
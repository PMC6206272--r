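get_conc <- function(profile) {
  if (inherits(profile, "cannabinoid_profile")) profile$concentrations
  else if (is.numeric(profile) && !is.null(names(profile))) profile
  else stop("expected a cannabinoid_profile or a named numeric vector")
}

#' Acid-equivalent concentrations of the eight fraction analytes
#'
#' Acids pass through unchanged; the neutral cannabinoids are multiplied by
#' the molecular-weight conversion factor of their alkyl class (C3: THCV,
#' CBDV; C5: THC, CBD) so acid and neutral forms can be summed on a common
#' decarboxylation-corrected basis. Fraction analytes absent from the
#' profile are treated as zero with a warning.
#'
#' @param profile A `cannabinoid_profile` or named concentration vector.
#' @param printed_constants Use the truncated printed factors 1.1536/1.1399
#'   instead of full precision.
#' @param registry,weights Passed to [conversion_factors()].
#' @return Named numeric vector over [fraction_analytes()], acid-equivalent
#'   concentrations.
#' @export
acid_equivalents <- function(profile, printed_constants = FALSE,
                             registry = analyte_registry(),
                             weights = atomic_weights()) {
  conc <- get_conc(profile)
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentration in profile")
  fa <- fraction_analytes()
  absent <- setdiff(fa, names(conc))
  if (length(absent) > 0L) {
    warning("fraction analyte(s) absent, treated as 0: ", paste(absent, collapse = ", "))
  }
  v <- vapply(fa, function(an) if (an %in% names(conc)) conc[[an]] else 0, numeric(1))
  f <- conversion_factors(printed = printed_constants, registry = registry,
                          weights = weights)
  v[c("THCV", "CBDV")] <- v[c("THCV", "CBDV")] * f[["C3"]]
  v[c("THC", "CBD")] <- v[c("THC", "CBD")] * f[["C5"]]
  v
}

#' Chemotype fraction statistics
#'
#' Computes the four chemotype fractions of the total cannabinoid
#' fraction:
#' \describe{
#'   \item{F_C3}{(THCVA + CBDVA + converted THCV + CBDV) / total x 100}
#'   \item{F_C5}{(THCA + CBDA + converted THC + CBD) / total x 100}
#'   \item{F_dicyclic}{(CBDVA + CBDA + converted CBDV + CBD) / total x 100}
#'   \item{F_tricyclic}{(THCVA + THCA + converted THCV + THC) / total x 100}
#' }
#' where `total` is the sum of acid-equivalent concentrations of the eight
#' fraction analytes. The pairs (F_C3, F_C5) and (F_dicyclic, F_tricyclic)
#' partition the same total, so each pair sums to 100 by construction.
#' CBGA, CBG, CBN and CBC are quantified by the pipeline but excluded from
#' the total and all fractions.
#'
#' @inheritParams acid_equivalents
#' @return Object of class `chemotype_fractions`: plant/stage metadata (if
#'   a profile was given), the four F values (%), and `total` (ug/mL
#'   acid-equivalent).
#' @export
#' @examples
#' compute_fractions(c(THCA = 2, THC = 1, CBDVA = 3, CBDV = 0.5))
compute_fractions <- function(profile, printed_constants = FALSE,
                              registry = analyte_registry(),
                              weights = atomic_weights()) {
  eq <- acid_equivalents(profile, printed_constants, registry, weights)
  total <- sum(eq)
  if (total <= 0) stop("no quantifiable fraction analytes (total acid-equivalent is 0)")
  c3 <- sum(eq[c("THCVA", "CBDVA", "THCV", "CBDV")])
  di <- sum(eq[c("CBDVA", "CBDA", "CBDV", "CBD")])
  meta <- if (inherits(profile, "cannabinoid_profile")) {
    profile[c("plant_id", "accession", "stage")]
  } else list(plant_id = NULL, accession = NULL, stage = NULL)
  structure(
    c(meta,
      list(F_C3 = 100 * c3 / total,
           F_C5 = 100 * (total - c3) / total,
           F_dicyclic = 100 * di / total,
           F_tricyclic = 100 * (total - di) / total,
           total = total)),
    class = "chemotype_fractions"
  )
}

#' @export
print.chemotype_fractions <- function(x, ...) {
  hdr <- paste(c(x$plant_id, x$stage), collapse = " / ")
  if (nzchar(hdr)) cat(hdr, "\n")
  cat(sprintf("  F_C3 %6.2f%%  F_C5 %6.2f%%  F_dicyclic %6.2f%%  F_tricyclic %6.2f%%  total %.3g ug/mL\n",
              x$F_C3, x$F_C5, x$F_dicyclic, x$F_tricyclic, x$total))
  invisible(x)
}

#' Log10 chemotype ratios
#'
#' log10 of F_dicyclic:F_tricyclic and F_C3:F_C5, with numerator and
#' denominator each clamped to at least `floor` (percent) so near-pure
#' homozygote chemotypes remain finite and plottable.
#'
#' @param fractions A `chemotype_fractions` object (or list with the four
#'   F fields).
#' @param floor Lower clamp in percent, > 0 (default 0.01).
#' @return List with `log10_di_tri` and `log10_c3_c5`.
#' @export
log_ratios <- function(fractions, floor = 0.01) {
  stopifnot(floor > 0)
  clamp <- function(v) max(v, floor)
  list(
    log10_di_tri = log10(clamp(fractions$F_dicyclic) / clamp(fractions$F_tricyclic)),
    log10_c3_c5 = log10(clamp(fractions$F_C3) / clamp(fractions$F_C5))
  )
}

#' Within-alkyl-class dicyclic:tricyclic ratios
#'
#' For heterozygote analysis: the dicyclic:tricyclic acid-equivalent ratio
#' computed separately inside the C5 pool ((CBDA + CBD_eq)/(THCA + THC_eq))
#' and the C3 pool ((CBDVA + CBDV_eq)/(THCVA + THCV_eq)), plus their
#' quotient `het_ratio` (C5 ratio over C3 ratio). A zero denominator
#' flags the plant as undefined (NA values, `undefined = TRUE`) so it can
#' be excluded from cohort means.
#'
#' @inheritParams acid_equivalents
#' @return List with `within_C5_di_tri`, `within_C3_di_tri`, `het_ratio`,
#'   `undefined`.
#' @export
within_class_ratios <- function(profile, printed_constants = FALSE,
                                registry = analyte_registry(),
                                weights = atomic_weights()) {
  eq <- acid_equivalents(profile, printed_constants, registry, weights)
  c5_tri <- sum(eq[c("THCA", "THC")])
  c3_tri <- sum(eq[c("THCVA", "THCV")])
  if (c5_tri == 0 || c3_tri == 0) {
    return(list(within_C5_di_tri = NA_real_, within_C3_di_tri = NA_real_,
                het_ratio = NA_real_, undefined = TRUE))
  }
  w5 <- sum(eq[c("CBDA", "CBD")]) / c5_tri
  w3 <- sum(eq[c("CBDVA", "CBDV")]) / c3_tri
  het <- if (w3 == 0) NA_real_ else w5 / w3
  list(within_C5_di_tri = w5, within_C3_di_tri = w3,
       het_ratio = het, undefined = is.na(het))
}

#' Classify B-locus zygosity from the dicyclic fraction
#'
#' Plants with F_dicyclic at or above `hi` are called homozygous for the
#' CBDA-synthase allele (dicyclic homozygote), at or below `lo` homozygous
#' for the THCA-synthase allele (tricyclic homozygote), and intermediate
#' chemotypes heterozygous. The 90% boundary itself counts as homozygous.
#'
#' @param f_dicyclic Numeric vector of F_dicyclic values (%).
#' @param lo,hi Thresholds in percent, `0 <= lo < hi <= 100`.
#' @return Factor with levels `homozygous_tricyclic`, `heterozygous`,
#'   `homozygous_dicyclic`.
#' @export
classify_b_locus <- function(f_dicyclic, lo = 10, hi = 90) {
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  out <- ifelse(f_dicyclic >= hi, "homozygous_dicyclic",
                ifelse(f_dicyclic <= lo, "homozygous_tricyclic", "heterozygous"))
  factor(out, levels = c("homozygous_tricyclic", "heterozygous", "homozygous_dicyclic"))
}

#' Fraction table for a set of merged profiles
#'
#' Applies [compute_fractions()], [log_ratios()] and [classify_b_locus()]
#' to a list of (replicate-merged) profiles and assembles the long
#' per-plant-per-stage fraction table used by the plasticity and
#' chemometrics stages.
#'
#' @param profiles List of `cannabinoid_profile` objects.
#' @param printed_constants,floor,lo,hi Passed through to the underlying
#'   functions.
#' @return data.frame with plant_id, accession, stage, the four F values,
#'   total, the two log10 ratios and the B-locus class.
#' @export
fractions_table <- function(profiles, printed_constants = FALSE,
                            floor = 0.01, lo = 10, hi = 90) {
  rows <- lapply(profiles, function(p) {
    fr <- compute_fractions(p, printed_constants = printed_constants)
    lr <- log_ratios(fr, floor = floor)
    data.frame(plant_id = p$plant_id,
               accession = if (is.null(p$accession)) NA_character_ else p$accession,
               stage = p$stage,
               F_C3 = fr$F_C3, F_C5 = fr$F_C5,
               F_dicyclic = fr$F_dicyclic, F_tricyclic = fr$F_tricyclic,
               total = fr$total,
               log10_di_tri = lr$log10_di_tri,
               log10_c3_c5 = lr$log10_c3_c5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$b_locus_class <- classify_b_locus(out$F_dicyclic, lo = lo, hi = hi)
  rownames(out) <- NULL
  out
}
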
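#' Fit a quadratic calibration curve
#'
#' Fits the detector response `area = a*conc^2 + b*conc + c` by least
#' squares to the calibration standards of one analyte, together with a
#' companion straight-line fit whose R-squared is kept as the linearity
#' diagnostic (`r2_linear`). The fitted quadratic must be strictly
#' increasing over the calibration range; a non-monotone response is a
#' fitting failure, because inversion would be ill-posed.
#'
#' @param points data.frame with columns `concentration_ug_ml` and
#'   `peak_area` (an `analyte` column, if present, must be homogeneous).
#' @param analyte Optional analyte code recorded on the curve.
#' @param fit_date Optional tag (calibrations are typically daily).
#' @return An object of class `calibration_curve` with elements
#'   `coefficients` (a, b, c), `valid_range`, `r2_linear`, `analyte`,
#'   `fit_date`.
#' @export
fit_calibration <- function(points, analyte = NULL, fit_date = NA_character_) {
  stopifnot(is.data.frame(points))
  need <- c("concentration_ug_ml", "peak_area")
  missing <- setdiff(need, names(points))
  if (length(missing) > 0L) {
    stop("calibration points missing column(s): ", paste(missing, collapse = ", "))
  }
  if ("analyte" %in% names(points)) {
    codes <- unique(points$analyte)
    if (length(codes) > 1L) stop("calibration points mix analytes: ",
                                 paste(codes, collapse = ", "))
    if (is.null(analyte)) analyte <- codes
  }
  conc <- as.numeric(points$concentration_ug_ml)
  area <- as.numeric(points$peak_area)
  if (any(!is.finite(conc)) || any(!is.finite(area))) stop("non-finite calibration data")
  if (any(conc <= 0)) stop("nominal concentrations must be > 0")
  if (any(area < 0)) stop("peak areas must be >= 0")
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct concentration levels to fit a quadratic")
  }
  quad <- stats::lm(area ~ conc + I(conc^2))
  lin <- stats::lm(area ~ conc)
  cf <- stats::coef(quad)
  a <- unname(cf[["I(conc^2)"]])
  b <- unname(cf[["conc"]])
  c0 <- unname(cf[["(Intercept)"]])
  rng <- range(conc)
  # quadratic derivative is linear in conc, so endpoint checks suffice
  if (2 * a * rng[1] + b <= 0 || 2 * a * rng[2] + b <= 0) {
    stop(sprintf("fitted response for %s is not strictly increasing on [%g, %g]; curve unusable",
                 if (is.null(analyte)) "analyte" else analyte, rng[1], rng[2]))
  }
  structure(
    list(analyte = analyte,
         coefficients = c(a = a, b = b, c = c0),
         valid_range = rng,
         r2_linear = 1 - sum(stats::resid(lin)^2) / sum((area - mean(area))^2),
         fit_date = fit_date),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Calibration curve%s: area = %.4g*conc^2 + %.4g*conc + %.4g\n",
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              cf[["a"]], cf[["b"]], cf[["c"]]))
  cat(sprintf("  range %g-%g ug/mL, linear R2 = %.5f\n",
              x$valid_range[1], x$valid_range[2], x$r2_linear))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Solves the fitted quadratic for concentration given observed peak
#' areas. Because the response is strictly increasing on the calibration
#' range there is a unique admissible root in `[0, 1.1 * range_max]`; the
#' 10% headroom tolerates areas marginally above the top standard, while
#' larger areas raise a saturation error. Concentrations below the lowest
#' standard (the working LOQ) are returned but flagged through the
#' `below_loq` attribute.
#'
#' @param area Numeric vector of peak areas (>= 0).
#' @param curve A `calibration_curve`.
#' @return Numeric vector of concentrations (ug/mL at the detector), with
#'   a logical attribute `below_loq`.
#' @export
invert_calibration <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  area <- as.numeric(area)
  if (any(!is.finite(area)) || any(area < 0)) stop("peak areas must be finite and >= 0")
  cf <- curve$coefficients
  a <- cf[["a"]]; b <- cf[["b"]]; c0 <- cf[["c"]]
  xmax <- 1.1 * curve$valid_range[2]
  resp <- function(x) a * x^2 + b * x + c0
  area_cap <- resp(xmax)
  tol <- 1e-9 * max(1, xmax)
  conc <- vapply(area, function(ar) {
    if (ar > area_cap + 1e-9 * max(1, abs(area_cap))) {
      stop(sprintf("peak area %g exceeds calibrated response at 1.1x range max (saturation)", ar))
    }
    if (ar <= resp(0)) return(0)  # below the fitted blank response: clamp to 0 (flagged below LOQ)
    if (abs(a) < 1e-12 * max(1, abs(b))) {
      x <- (ar - c0) / b
    } else {
      disc <- b^2 - 4 * a * (c0 - ar)
      if (disc < 0) stop(sprintf("no real root for peak area %g within calibrated window", ar))
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      # keep the root on the increasing branch of the parabola
      roots <- roots[2 * a * roots + b > 0]
      roots <- roots[roots >= -tol & roots <= xmax + tol]
      if (length(roots) == 0L) {
        stop(sprintf("no admissible root for peak area %g in [0, %g]", ar, xmax))
      }
      x <- roots[1]
    }
    max(x, 0)
  }, numeric(1))
  attr(conc, "below_loq") <- conc < curve$valid_range[1]
  conc
}

#' Quantify one sample extract
#'
#' Converts the peak areas of one injected (diluted) extract into
#' concentrations in the undiluted extract, multiplying the inverted
#' calibration value by the dilution factor. When tissue mass and solvent
#' volume are supplied, weight-per-weight concentrations
#' (mg analyte per g tissue) are reported as well.
#'
#' @param areas Named numeric vector of peak areas, names are analyte codes.
#' @param curves Named list of `calibration_curve` objects.
#' @param extract List (or one-row data.frame) describing the extract:
#'   `plant_id`, `stage`, and optionally `accession`, `replicate`,
#'   `dilution_factor` (default 5), `tissue_mass_mg`, `solvent_volume_ml`.
#' @return An object of class `cannabinoid_profile`: plant/stage metadata,
#'   `concentrations` (ug/mL undiluted extract), optional `mg_per_g`, and
#'   the `below_loq` flags.
#' @export
quantify_sample <- function(areas, curves, extract) {
  stopifnot(is.numeric(areas), !is.null(names(areas)))
  extract <- as.list(extract)
  dil <- extract$dilution_factor
  if (is.null(dil) || is.na(dil)) dil <- 5
  if (dil < 1) stop("dilution_factor must be >= 1")
  missing <- setdiff(names(areas), names(curves))
  if (length(missing) > 0L) {
    stop("no calibration curve for analyte(s): ", paste(missing, collapse = ", "))
  }
  conc <- numeric(length(areas))
  names(conc) <- names(areas)
  loq <- logical(length(areas))
  names(loq) <- names(areas)
  for (an in names(areas)) {
    x <- invert_calibration(areas[[an]], curves[[an]])
    conc[[an]] <- x * dil
    loq[[an]] <- attr(x, "below_loq")
  }
  mg_per_g <- NULL
  tm <- extract$tissue_mass_mg
  sv <- extract$solvent_volume_ml
  if (!is.null(tm) && !is.null(sv) && !is.na(tm) && !is.na(sv)) {
    if (tm <= 0 || sv <= 0) stop("tissue_mass_mg and solvent_volume_ml must be > 0")
    mg_per_g <- conc * sv / tm  # ug/mL * mL / mg == ug/mg == mg/g
  }
  structure(
    list(plant_id = extract$plant_id,
         accession = extract$accession,
         stage = extract$stage,
         replicate = extract$replicate,
         concentrations = conc,
         mg_per_g = mg_per_g,
         below_loq = loq),
    class = "cannabinoid_profile"
  )
}

#' Average duplicate extraction replicates
#'
#' Per-analyte arithmetic mean of two extraction replicates of the same
#' plant and stage. The replicate pair is retained on the merged profile
#' for repeatability diagnostics.
#'
#' @param rep1,rep2 `cannabinoid_profile` objects for the same plant/stage.
#' @return Merged `cannabinoid_profile` (replicate index dropped).
#' @export
merge_replicates <- function(rep1, rep2) {
  stopifnot(inherits(rep1, "cannabinoid_profile"), inherits(rep2, "cannabinoid_profile"))
  if (!identical(rep1$plant_id, rep2$plant_id) || !identical(rep1$stage, rep2$stage)) {
    stop(sprintf("replicates disagree on plant/stage: %s/%s vs %s/%s",
                 rep1$plant_id, rep1$stage, rep2$plant_id, rep2$stage))
  }
  analytes <- union(names(rep1$concentrations), names(rep2$concentrations))
  get <- function(p, an) if (an %in% names(p$concentrations)) p$concentrations[[an]] else 0
  conc <- vapply(analytes, function(an) (get(rep1, an) + get(rep2, an)) / 2, numeric(1))
  merged <- rep1
  merged$replicate <- NA_integer_
  merged$concentrations <- conc
  merged$mg_per_g <- NULL
  merged$below_loq <- NULL
  merged$replicate_pair <- list(rep1 = rep1$concentrations, rep2 = rep2$concentrations)
  merged
}

#' Replicate repeatability of the fraction statistics
#'
#' Coefficient of determination between duplicate extraction replicates,
#' computed per fraction statistic across plants as the squared Pearson
#' correlation of the paired values (symmetric in the replicates).
#'
#' @param rep1,rep2 data.frames with the same rows (plants) and the
#'   fraction columns to compare (default the four F statistics present in
#'   both).
#' @param statistics Columns to compare.
#' @return Named numeric vector of R-squared values.
#' @export
replicate_repeatability <- function(rep1, rep2,
                                    statistics = intersect(
                                      c("F_C3", "F_C5", "F_dicyclic", "F_tricyclic"),
                                      intersect(names(rep1), names(rep2)))) {
  stopifnot(is.data.frame(rep1), is.data.frame(rep2), nrow(rep1) == nrow(rep2))
  if (nrow(rep1) < 3L) stop("need at least 3 replicate pairs")
  if (length(statistics) == 0L) stop("no fraction statistics in common")
  vapply(statistics, function(s) {
    x <- rep1[[s]]; y <- rep2[[s]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop(sprintf("R-squared undefined for constant '%s' values", s))
    }
    stats::cor(x, y)^2
  }, numeric(1))
}
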
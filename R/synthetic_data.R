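#' Default accession plan of the synthetic diversity panel
#'
#' Twenty accessions totalling 99 plants, three to seven plants each, with
#' region-of-provenance labels carried as plain metadata (no
#' region-to-chemotype effect is modelled).
#'
#' @return data.frame with accession, n_plants, provenance.
#' @export
default_accession_plan <- function() {
  data.frame(
    accession = c("A", "B", "C", "D", "E", "F", "G", "I", "J", "K",
                  "L", "M", "O", "P", "Q", "R", "S", "T", "U", "X"),
    n_plants = c(3L, 4L, 5L, 3L, 5L, 5L, 6L, 6L, 6L, 4L,
                 4L, 7L, 6L, 6L, 5L, 6L, 3L, 5L, 7L, 3L),
    provenance = c("Southern Asia", "Eastern Asia", "Eastern Asia",
                   "Eastern Asia", "Eastern Asia", "Eastern Asia",
                   "Eastern Asia", "Southern Asia", "Eastern Asia",
                   "Eastern Asia", "Eastern Asia", "Eastern Asia",
                   "Eastern Asia", "Eastern Asia", "Caribbean",
                   "Southern Asia", "Southern Africa", "Western Asia",
                   "Eastern Africa", "Eastern Asia"),
    stringsAsFactors = FALSE
  )
}

#' Default generator configuration
#'
#' The generator emulates a diversity panel segregating at a codominant B
#' locus (THCAS/CBDAS) with a latent three-class propyl (C3) trait:
#' \itemize{
#'   \item B-locus genotype weights 0.40 / 0.20 / 0.40 for tricyclic
#'     homozygote / heterozygote / dicyclic homozygote (about 20
#'     heterozygotes in a 99-plant panel);
#'   \item latent F_dicyclic drawn per genotype as a truncated normal on
#'     [0.5, 7] (hom. tricyclic), [25, 75] (het.), [93, 99.5]
#'     (hom. dicyclic), centred at the range midpoint with SD = width/6
#'     -- a trimodal distribution with discrete modes;
#'   \item latent F_C3 classes low/intermediate/high with weights
#'     0.50/0.30/0.20 and overlapping truncated-normal ranges [0.4, 20],
#'     [18, 65], [60, 92] -- a continuum of three overlapping classes;
#'   \item per-stage biological noise SD 1.5 percentage points; three
#'     designated outlier heterozygotes whose F_dicyclic drifts 25
#'     percentage points toward parity between vegetative and maturation;
#'   \item within-class dicyclic skew: the C5 dicyclic:tricyclic odds of a
#'     heterozygote equal `het_skew` (1.44) times its C3 odds;
#'   \item abundance and noise: total acid-equivalent 20-150 ug/mL in the
#'     undiluted extract, 90:10 acid:neutral split, duplicate extraction
#'     replicates at 2% multiplicative peak-area RSD, standards at 1% RSD,
#'     1:5 injection dilution, six standard levels 0.032-100 ug/mL, a mild
#'     positive quadratic detector response per analyte.
#' }
#'
#' @param seed Integer seed; all randomness in [simulate_panel()] flows
#'   from it.
#' @return List of class `generator_config`.
#' @export
default_generator_config <- function(seed = 1L) {
  reg <- analyte_registry()
  # per-analyte detector response truth: slight sensitivity spread, mild
  # positive curvature, zero intercept
  calib <- lapply(seq_len(nrow(reg)), function(i) {
    c(a = 0.15 + 0.01 * i, b = 900 + 25 * i, c = 0)
  })
  names(calib) <- reg$code
  structure(list(
    seed = as.integer(seed),
    accessions = default_accession_plan(),
    b_locus_weights = c(homozygous_tricyclic = 0.40, heterozygous = 0.20,
                        homozygous_dicyclic = 0.40),
    dicyclic_ranges = list(homozygous_tricyclic = c(0.5, 7),
                           heterozygous = c(25, 75),
                           homozygous_dicyclic = c(93, 99.5)),
    c3_class_weights = c(low = 0.50, intermediate = 0.30, high = 0.20),
    c3_class_ranges = list(low = c(0.4, 20), intermediate = c(18, 65),
                           high = c(60, 92)),
    stage_noise_sd = 1.5,
    outlier_het_count = 3L,
    outlier_drift = 25,
    het_skew = 1.44,
    total_range = c(20, 150),
    acid_fraction = 0.9,
    minor_fraction = 0.02,
    replicate_rsd = 0.02,
    standards_rsd = 0.01,
    dilution_factor = 5,
    standard_levels = c(0.032, 0.16, 0.8, 4, 20, 100),
    calibration = calib
  ), class = "generator_config")
}

#' Draw plant genotypes for the panel
#'
#' One row per plant: accession, plant id (accession letter plus 01..),
#' B-locus genotype, latent F_dicyclic, latent C3 class and latent F_C3,
#' and the outlier flag (the first `outlier_het_count` heterozygotes in id
#' order are designated developmental outliers).
#'
#' @param config A `generator_config`.
#' @return data.frame of genotypes (the panel truth at the genotype level).
#' @export
simulate_genotypes <- function(config = default_generator_config()) {
  plan <- config$accessions
  n <- sum(plan$n_plants)
  acc <- rep(plan$accession, plan$n_plants)
  idx <- unlist(lapply(plan$n_plants, seq_len))
  plant_id <- paste0(acc, sprintf("%02d", idx))
  b <- sample(names(config$b_locus_weights), n, replace = TRUE,
              prob = config$b_locus_weights)
  f_di <- vapply(b, function(g) {
    rlatent(1, config$dicyclic_ranges[[g]])
  }, numeric(1))
  cls <- sample(names(config$c3_class_weights), n, replace = TRUE,
                prob = config$c3_class_weights)
  f_c3 <- vapply(cls, function(g) {
    rlatent(1, config$c3_class_ranges[[g]])
  }, numeric(1))
  het <- which(b == "heterozygous")
  outliers <- head(het, config$outlier_het_count)
  data.frame(
    plant_id = plant_id,
    accession = acc,
    provenance = rep(plan$provenance, plan$n_plants),
    b_locus = b,
    c3_class = cls,
    latent_F_dicyclic = unname(f_di),
    latent_F_C3 = unname(f_c3),
    is_outlier = seq_len(n) %in% outliers,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# Latent class value on a stated range: truncated normal centred at the
# range midpoint with SD = width/6 (the usual "range ~ +/- 3 SD"
# convention), drawn by inverse-CDF so the support is exactly the range.
rlatent <- function(n, range) {
  mu <- mean(range)
  sd <- diff(range) / 6
  plo <- stats::pnorm(range[1], mu, sd)
  phi <- stats::pnorm(range[2], mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Realized per-stage fraction truth
#'
#' Expands genotypes to per-plant-per-stage fraction values: latent value
#' plus Normal(0, stage_noise_sd) biological noise, clipped to [0, 100].
#' Designated outlier heterozygotes additionally drift toward parity
#' (50%) in F_dicyclic: no drift at vegetative, half at flowering, the
#' full `outlier_drift` (capped at parity) at maturation.
#'
#' @param genotypes From [simulate_genotypes()].
#' @param config A `generator_config`.
#' @return data.frame with one row per plant x stage: realized F_dicyclic
#'   and F_C3 plus a per-stage total abundance draw (ug/mL acid-equivalent
#'   in the undiluted extract).
#' @export
simulate_fraction_truth <- function(genotypes, config = default_generator_config()) {
  stages <- c("vegetative", "flowering", "maturation")
  drift_frac <- c(vegetative = 0, flowering = 0.5, maturation = 1)
  rows <- lapply(stages, function(st) {
    lat_di <- genotypes$latent_F_dicyclic
    drift <- ifelse(genotypes$is_outlier,
                    sign(50 - lat_di) *
                      pmin(config$outlier_drift * drift_frac[[st]],
                           abs(50 - lat_di)),
                    0)
    n <- nrow(genotypes)
    data.frame(
      plant_id = genotypes$plant_id,
      accession = genotypes$accession,
      stage = st,
      F_dicyclic = clip01(lat_di + drift + stats::rnorm(n, 0, config$stage_noise_sd)),
      F_C3 = clip01(genotypes$latent_F_C3 + stats::rnorm(n, 0, config$stage_noise_sd)),
      total = stats::runif(n, config$total_range[1], config$total_range[2]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decompose target fractions into the eight analyte concentrations
#'
#' Given target F_C3 and F_dicyclic (percent), a total acid-equivalent
#' abundance, the heterozygote skew s, and the acid:neutral split, solves
#' the 2 x 2 allocation over \{C3, C5\} x \{dicyclic, tricyclic\} pools such
#' that the C5 dicyclic:tricyclic odds equal s times the C3 odds. Writing
#' x for the C3-dicyclic pool, p3/pd for the target fractions and T for
#' the total, the skew constraint
#' `(pd*T - x)/((1 - p3 - pd)*T + x) = s * x/(p3*T - x)` reduces to the
#' quadratic `(1 - s)x^2 - ((p3 + pd) + s(1 - p3 - pd))T x + p3*pd*T^2 = 0`,
#' whose unique root in `[max(0, (p3 + pd - 1)T), min(p3, pd)T]` is taken
#' (the linear s = 1 case gives x = p3*pd*T, i.e. independence). Each pool
#' is then split `acid_fraction : (1 - acid_fraction)` on the
#' acid-equivalent scale, and neutral concentrations are divided by their
#' conversion factor, so [compute_fractions()] recovers the targets
#' exactly.
#'
#' @param f_c3,f_dicyclic Target fractions in percent.
#' @param total Total acid-equivalent concentration (ug/mL).
#' @param het_skew Skew s > 0.
#' @param acid_fraction Acid share of each pool, in [0, 1].
#' @param factors Conversion factors, see [conversion_factors()].
#' @return Named numeric vector over [fraction_analytes()] (native
#'   concentrations, not acid equivalents).
#' @export
decompose_fractions <- function(f_c3, f_dicyclic, total, het_skew = 1,
                                acid_fraction = 0.9,
                                factors = conversion_factors()) {
  stopifnot(total > 0, het_skew > 0, acid_fraction >= 0, acid_fraction <= 1,
            f_c3 >= 0, f_c3 <= 100, f_dicyclic >= 0, f_dicyclic <= 100)
  p3 <- f_c3 / 100; pd <- f_dicyclic / 100; s <- het_skew; T <- total
  lo <- max(0, (p3 + pd - 1) * T)
  hi <- min(p3, pd) * T
  if (hi <= lo + 1e-15 * T) {
    x <- lo  # degenerate pool (a zero row or column of the 2x2 table)
  } else if (abs(1 - s) < 1e-12) {
    x <- p3 * pd * T
  } else {
    A <- 1 - s
    B <- -((p3 + pd) + s * (1 - p3 - pd)) * T
    C <- p3 * pd * T^2
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("infeasible fraction decomposition")
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    tol <- 1e-9 * T
    cand <- roots[roots >= lo - tol & roots <= hi + tol]
    if (length(cand) == 0L) stop("infeasible fraction decomposition")
    if (length(cand) > 1L) {
      # at most one root is strictly interior; prefer it over a boundary graze
      cand <- cand[which.max(pmin(cand - lo, hi - cand))]
    }
    x <- min(max(cand, lo), hi)
  }
  a3d <- x
  a3t <- p3 * T - x
  a5d <- pd * T - x
  a5t <- (1 - p3 - pd) * T + x
  pools <- c(a3d = a3d, a3t = a3t, a5d = a5d, a5t = a5t)
  if (any(pools < -1e-9 * T)) stop("infeasible fraction decomposition")
  pools <- pmax(pools, 0)
  q <- acid_fraction
  c(THCA = q * pools[["a5t"]],
    THC = (1 - q) * pools[["a5t"]] / factors[["C5"]],
    CBDA = q * pools[["a5d"]],
    CBD = (1 - q) * pools[["a5d"]] / factors[["C5"]],
    THCVA = q * pools[["a3t"]],
    THCV = (1 - q) * pools[["a3t"]] / factors[["C3"]],
    CBDVA = q * pools[["a3d"]],
    CBDV = (1 - q) * pools[["a3d"]] / factors[["C3"]])
}

detector_area <- function(conc, coefs) {
  coefs[["a"]] * conc^2 + coefs[["b"]] * conc + coefs[["c"]]
}

#' Simulate a full synthetic diversity panel
#'
#' Generates the complete study stand-in: plant genotypes, realized
#' per-stage fraction truth, per-analyte concentrations, a daily
#' calibration-standards table, and a long-format sample table of peak
#' areas for duplicate extraction replicates at every plant x stage --
#' the two CSV dialects consumed by [read_standards()] and
#' [read_samples()]. All randomness flows from `config$seed`; the same
#' seed reproduces the tables exactly.
#'
#' Beyond the eight fraction analytes, small amounts of CBGA, CBG, CBN and
#' CBC (together `minor_fraction` of the total) are added so the full
#' 12-analyte panel is exercised; they do not enter the fraction
#' statistics.
#'
#' @param config A `generator_config`, see [default_generator_config()].
#' @return List of class `synthetic_panel`: `genotypes`, `truth` (per
#'   plant x stage fractions and concentrations), `standards`, `samples`,
#'   `config`.
#' @export
simulate_panel <- function(config = default_generator_config()) {
  stopifnot(inherits(config, "generator_config") || is.list(config))
  factors <- conversion_factors()
  reg <- analyte_registry()
  with_preserved_seed(config$seed, {
    genotypes <- simulate_genotypes(config)
    truth <- simulate_fraction_truth(genotypes, config)

    # per plant x stage analyte concentrations (undiluted extract, ug/mL)
    minor_split <- c(CBGA = 0.4, CBG = 0.1, CBN = 0.25, CBC = 0.25)
    conc_rows <- lapply(seq_len(nrow(truth)), function(i) {
      r <- truth[i, ]
      conc8 <- decompose_fractions(r$F_C3, r$F_dicyclic, r$total,
                                   het_skew = config$het_skew,
                                   acid_fraction = config$acid_fraction,
                                   factors = factors)
      minors <- config$minor_fraction * r$total * minor_split
      c(conc8, minors)
    })
    conc_mat <- do.call(rbind, conc_rows)

    # calibration standards with multiplicative detector noise
    std_rows <- lapply(reg$code, function(an) {
      lv <- config$standard_levels
      mu <- detector_area(lv, config$calibration[[an]])
      data.frame(analyte = an, concentration_ug_ml = lv,
                 peak_area = mu * (1 + stats::rnorm(length(lv), 0, config$standards_rsd)),
                 fit_date = "day1", stringsAsFactors = FALSE)
    })
    standards <- do.call(rbind, std_rows)

    # long sample table: 2 extraction replicates per plant x stage
    analytes <- colnames(conc_mat)
    n_obs <- nrow(truth)
    sample_rows <- vector("list", n_obs * 2L)
    for (i in seq_len(n_obs)) {
      r <- truth[i, ]
      fresh <- r$stage != "maturation"  # fresh leaf: 250 mg / 1 mL; dried: 250 mg / 25 mL
      for (rep_i in 1:2) {
        diluted <- conc_mat[i, ] / config$dilution_factor
        mu <- vapply(analytes, function(an) {
          detector_area(diluted[[an]], config$calibration[[an]])
        }, numeric(1))
        area <- mu * (1 + stats::rnorm(length(mu), 0, config$replicate_rsd))
        sample_rows[[(i - 1L) * 2L + rep_i]] <- data.frame(
          sample_id = paste(r$plant_id, r$stage, rep_i, sep = "_"),
          plant_id = r$plant_id,
          accession = r$accession,
          stage = r$stage,
          replicate = rep_i,
          analyte = analytes,
          peak_area = unname(area),
          dilution_factor = config$dilution_factor,
          tissue_mass_mg = 250,
          solvent_volume_ml = if (fresh) 1 else 25,
          stringsAsFactors = FALSE)
      }
    }
    samples <- do.call(rbind, sample_rows)
    rownames(samples) <- NULL

    truth_conc <- cbind(truth, as.data.frame(conc_mat))
    structure(list(genotypes = genotypes, truth = truth_conc,
                   standards = standards, samples = samples,
                   config = config),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d plants / %d accessions, %d sample rows, seed %d\n",
              length(unique(x$genotypes$plant_id)),
              length(unique(x$genotypes$accession)),
              nrow(x$samples), x$config$seed))
  invisible(x)
}

#' Occupancy of the three B-locus chemotype modes
#'
#' Applies [classify_b_locus()] to maturation-stage F_dicyclic values and
#' tabulates the three modes of the dicyclic:tricyclic distribution.
#'
#' @param fractions data.frame with `stage` and `F_dicyclic` columns
#'   (truth or pipeline-recovered), >= 10 plants.
#' @param lo,hi Classification thresholds in percent.
#' @return Named integer vector of counts over the three modes.
#' @export
trimodality_check <- function(fractions, lo = 10, hi = 90) {
  mat <- fractions[fractions$stage == "maturation", ]
  if (nrow(mat) < 10L) stop("need at least 10 plants")
  table(classify_b_locus(mat$F_dicyclic, lo = lo, hi = hi))
}
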
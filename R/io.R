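STAGES <- c("vegetative", "flowering", "maturation")

normalize_stage <- function(stage) {
  s <- tolower(trimws(as.character(stage)))
  s[s == "1008"] <- "vegetative"  # decimal growth-stage code for the fourth leaf pair
  if (any(s == "2202")) {
    stop("growth-stage code 2202 is ambiguous (used for both flowering and maturation); ",
         "use the stage names instead")
  }
  bad <- setdiff(unique(s), STAGES)
  if (length(bad) > 0L) {
    stop("unknown developmental stage(s): ", paste(bad, collapse = ", "))
  }
  s
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
}

check_analytes <- function(codes, registry = analyte_registry()) {
  bad <- which(!codes %in% registry$code)
  if (length(bad) > 0L) {
    stop(sprintf("unknown analyte code(s) %s at row(s) %s",
                 paste(unique(codes[bad]), collapse = ", "),
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
}

read_chemovar_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read a calibration-standards CSV
#'
#' Expected dialect: comma-separated, header row, UTF-8, "." decimal;
#' columns `analyte`, `concentration_ug_ml`, `peak_area` and optionally
#' `fit_date`. Lines starting with `#` are metadata comments.
#'
#' @param path File path.
#' @return data.frame of calibration points.
#' @export
read_standards <- function(path) {
  df <- read_chemovar_csv(path)
  check_columns(df, c("analyte", "concentration_ug_ml", "peak_area"), "standards CSV")
  check_analytes(df$analyte)
  if (any(df$concentration_ug_ml <= 0)) stop("standard concentrations must be > 0")
  if (any(df$peak_area < 0)) stop("standard peak areas must be >= 0")
  if (!"fit_date" %in% names(df)) df$fit_date <- NA_character_
  df
}

#' Read a long-format samples CSV
#'
#' One row per sample x analyte peak area. Required columns: `sample_id`,
#' `plant_id`, `accession`, `stage`, `replicate`, `analyte`, `peak_area`,
#' `dilution_factor`; optional `tissue_mass_mg`, `solvent_volume_ml`.
#' Stage names are normalized (growth-stage code 1008 is accepted as
#' vegetative); duplicate (plant, stage, replicate, analyte) rows are an
#' error.
#'
#' @param path File path.
#' @return data.frame of sample peak areas.
#' @export
read_samples <- function(path) {
  df <- read_chemovar_csv(path)
  check_columns(df, c("sample_id", "plant_id", "accession", "stage", "replicate",
                      "analyte", "peak_area", "dilution_factor"), "samples CSV")
  check_analytes(df$analyte)
  df$stage <- normalize_stage(df$stage)
  key <- paste(df$plant_id, df$stage, df$replicate, df$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (plant, stage, replicate, analyte) row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  if (any(df$peak_area < 0)) stop("peak areas must be >= 0")
  df
}

#' Write a data.frame as a chemovar CSV
#'
#' Plain comma-separated output with a leading `#` metadata comment
#' recording the package version and, if given, the seed -- readable back
#' by the `read_*` functions, with numerics preserved to full precision.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, the path.
#' @export
write_chemovar_csv <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- sprintf("# chemovar %s%s",
                  as.character(utils::packageVersion("chemovar")),
                  if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full chemotyping pipeline
#'
#' Chains the analysis end to end: fit daily calibration curves per
#' analyte, invert sample peak areas to concentrations (dilution
#' back-corrected), compute per-replicate fractions and their
#' repeatability, average duplicate extraction replicates, build the
#' fraction table (with log ratios and B-locus classes), run the four
#' developmental-stability regressions plus truncated stepwise residual
#' deletion, and categorize chemotypes by seeded k-means with elbow
#' selection of k.
#'
#' @param samples Samples data.frame or CSV path (see [read_samples()]).
#' @param standards Standards data.frame or CSV path (see [read_standards()]).
#' @param printed_constants Use the truncated printed conversion factors.
#' @param truncate_lo,truncate_hi Truncation bounds (percent) for the
#'   stepwise-deletion analysis.
#' @param delete_steps Points removed by stepwise deletion per statistic.
#' @param k_max,seed,restarts Clustering parameters.
#' @param log_floor Floor (percent) for the log ratios.
#' @return List of class `chemovar_report` with elements `curves`,
#'   `repeatability`, `fractions`, `stability`, `deletion`, `clustering`,
#'   `counts`.
#' @export
run_pipeline <- function(samples, standards,
                         printed_constants = FALSE,
                         truncate_lo = 10, truncate_hi = 90,
                         delete_steps = 3L,
                         k_max = 8L, seed = 17L, restarts = 50L,
                         log_floor = 0.01) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(standards)) standards <- read_standards(standards)

  curves <- lapply(split(standards, standards$analyte), function(pts) {
    fit_calibration(pts, fit_date = pts$fit_date[1])
  })

  # replicate-level profiles
  key_cols <- c("plant_id", "accession", "stage", "replicate")
  groups <- split(samples, samples[key_cols], drop = TRUE)
  rep_profiles <- lapply(groups, function(g) {
    areas <- stats::setNames(g$peak_area, g$analyte)
    extract <- as.list(g[1, c(key_cols, "dilution_factor",
                              intersect(c("tissue_mass_mg", "solvent_volume_ml"),
                                        names(g)))])
    quantify_sample(areas, curves, extract)
  })

  # repeatability of the fraction statistics between duplicate replicates
  rep_key <- vapply(rep_profiles, function(p) paste(p$plant_id, p$stage, sep = "\r"),
                    character(1))
  rep_idx <- vapply(rep_profiles, function(p) as.integer(p$replicate), integer(1))
  frac_of <- function(p) {
    fr <- compute_fractions(p, printed_constants = printed_constants)
    data.frame(plant_id = p$plant_id, stage = p$stage, F_C3 = fr$F_C3,
               F_C5 = fr$F_C5, F_dicyclic = fr$F_dicyclic,
               F_tricyclic = fr$F_tricyclic, stringsAsFactors = FALSE)
  }
  repeatability <- NULL
  if (all(c(1L, 2L) %in% rep_idx)) {
    f1 <- do.call(rbind, lapply(rep_profiles[rep_idx == 1L], frac_of))
    f2 <- do.call(rbind, lapply(rep_profiles[rep_idx == 2L], frac_of))
    f1 <- f1[order(f1$plant_id, f1$stage), ]
    f2 <- f2[order(f2$plant_id, f2$stage), ]
    if (nrow(f1) == nrow(f2) &&
        all(f1$plant_id == f2$plant_id) && all(f1$stage == f2$stage)) {
      repeatability <- do.call(rbind, lapply(STAGES, function(st) {
        r2 <- replicate_repeatability(f1[f1$stage == st, ], f2[f2$stage == st, ])
        data.frame(stage = st, t(r2), stringsAsFactors = FALSE)
      }))
    }
  }

  # merge duplicate replicates, tolerate singletons
  merged <- lapply(split(seq_along(rep_profiles), rep_key), function(ix) {
    if (length(ix) >= 2L) {
      merge_replicates(rep_profiles[[ix[1]]], rep_profiles[[ix[2]]])
    } else rep_profiles[[ix[1]]]
  })

  fractions <- fractions_table(merged, printed_constants = printed_constants,
                               floor = log_floor)
  fractions <- fractions[order(fractions$plant_id, match(fractions$stage, STAGES)), ]
  rownames(fractions) <- NULL

  stability <- stage_stability_report(fractions)

  deletion <- lapply(c(F_dicyclic = "F_dicyclic", F_C3 = "F_C3"), function(stat) {
    wide <- stage_series(fractions, stat)
    kept <- truncate_parity(wide, lo = truncate_lo, hi = truncate_hi)
    steps <- min(delete_steps, max(nrow(kept) - 2L, 0L))
    list(n_before = nrow(wide), n_after = nrow(kept),
         trace = stepwise_residual_deletion(kept$vegetative, kept$maturation,
                                            ids = kept$plant_id, n_steps = steps))
  })

  clustering <- lapply(c(F_dicyclic = "F_dicyclic", F_C3 = "F_C3"), function(stat) {
    wide <- stage_series(fractions, stat)
    curve <- criterion_curve(wide, k_max = min(k_max, nrow(wide)),
                             seed = seed, restarts = restarts)
    sel <- select_k(curve)
    model <- label_classes(chemotype_kmeans(wide, k = sel$k, seed = seed,
                                            restarts = restarts))
    list(curve = curve, selected_k = sel, model = model)
  })

  structure(
    list(curves = curves,
         repeatability = repeatability,
         fractions = fractions,
         stability = stability,
         deletion = deletion,
         clustering = clustering,
         counts = list(samples = nrow(samples),
                       profiles = length(rep_profiles),
                       plants = length(unique(fractions$plant_id))),
         params = list(printed_constants = printed_constants,
                       truncate = c(truncate_lo, truncate_hi),
                       delete_steps = delete_steps, k_max = k_max,
                       seed = seed, restarts = restarts, log_floor = log_floor)),
    class = "chemovar_report"
  )
}

#' @export
print.chemovar_report <- function(x, ...) {
  cat(sprintf("chemovar pipeline report: %d plants, %d sample rows\n",
              x$counts$plants, x$counts$samples))
  cat("\nDevelopmental stability (through-origin regressions):\n")
  print(x$stability, row.names = FALSE)
  for (stat in names(x$clustering)) {
    cl <- x$clustering[[stat]]
    cat(sprintf("\n%s clustering: elbow k = %d%s\n", stat, cl$selected_k$k,
                if (cl$selected_k$low_confidence) " (low confidence)" else ""))
  }
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Emits `fractions.csv`, `plasticity.json`, `clusters.json` and
#' `summary.txt`.
#'
#' @param report A `chemovar_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "chemovar_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- report$params$seed
  write_chemovar_csv(report$fractions, file.path(dir, "fractions.csv"), seed = seed)
  plast <- list(
    stability = report$stability,
    deletion = lapply(report$deletion, function(d) {
      list(n_before = d$n_before, n_after = d$n_after,
           trace = d$trace$trace, baseline_r2 = d$trace$baseline_r2,
           final_r2 = d$trace$final_r2,
           ss_res_reduction_pct = d$trace$ss_res_reduction_pct,
           delta_r2 = d$trace$delta_r2)
    }))
  jsonlite::write_json(plast, file.path(dir, "plasticity.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  clus <- lapply(report$clustering, function(cl) {
    list(criterion_curve = as.list(cl$curve),
         selected_k = cl$selected_k$k,
         low_confidence = cl$selected_k$low_confidence,
         centroids = unname(apply(cl$model$centroids, 1, as.list)),
         assignments = as.list(cl$model$assignments),
         class_labels = cl$model$class_labels,
         class_ranges = lapply(cl$model$class_ranges, as.list))
  })
  jsonlite::write_json(clus, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("chemovar %s report (seed %s)",
            as.character(utils::packageVersion("chemovar")), seed),
    sprintf("plants: %d, sample rows: %d", report$counts$plants,
            report$counts$samples),
    sprintf("stability R2: %s",
            paste(sprintf("%s/%s %.4f", report$stability$statistic,
                          report$stability$early_stage,
                          report$stability$r_squared), collapse = "; ")),
    sprintf("selected k: %s",
            paste(sprintf("%s=%d", names(report$clustering),
                          vapply(report$clustering,
                                 function(cl) cl$selected_k$k, integer(1))),
                  collapse = ", ")))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
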
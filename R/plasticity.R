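#' Through-origin regression
#'
#' Least-squares regression of maturation-stage fractions on earlier-stage
#' fractions with the intercept omitted (the fitted line is constrained
#' through the origin). With no intercept the conventional statistics are
#' computed on the uncentered total sum of squares: slope = sum(xy)/sum(x^2),
#' R2 = 1 - SSres/sum(y^2), F = (n-1)(sum(y^2) - SSres)/SSres on (1, n-1)
#' degrees of freedom. These match `summary(lm(y ~ x + 0))`, which backs
#' the fit.
#'
#' @param x,y Numeric vectors of equal length >= 2 (percent fractions).
#' @return Object of class `origin_regression` with slope, r_squared,
#'   f_statistic, df, p_value, n, ss_res, residuals, fitted.
#' @export
regress_through_origin <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in x or y")
  if (all(x == 0)) stop("all-zero x: through-origin slope undefined")
  fit <- stats::lm(y ~ x + 0)
  slope <- unname(stats::coef(fit)[["x"]])
  res <- unname(stats::resid(fit))
  ss_res <- sum(res^2)
  ss_tot <- sum(y^2)
  r2 <- 1 - ss_res / ss_tot
  f <- if (ss_res > 0) (n - 1) * (ss_tot - ss_res) / ss_res else Inf
  p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  structure(
    list(slope = slope, r_squared = r2, f_statistic = f,
         df = c(1L, n - 1L), p_value = p, n = n,
         ss_res = ss_res, residuals = res, fitted = slope * x),
    class = "origin_regression"
  )
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("Through-origin regression (n = %d): slope = %.4f, R2 = %.4f\n",
              x$n, x$slope, x$r_squared))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$df[1], x$df[2], x$f_statistic,
              x$p_value))
  invisible(x)
}

#' Truncate a panel to non-extreme chemotypes
#'
#' Retains plants whose maturation-stage fraction lies within `[lo, hi]`
#' percent; removal uses the strict inequalities (> hi or < lo), so
#' boundary values are retained. Removing the near-pure homozygotes leaves
#' the intermediate chemotypes whose developmental behaviour is of
#' interest.
#'
#' @param series data.frame with a `maturation` column (percent), e.g. the
#'   wide stage table from [stage_series()].
#' @param lo,hi Retention bounds in percent, `lo < hi`.
#' @return Filtered data.frame (idempotent).
#' @export
truncate_parity <- function(series, lo = 10, hi = 90) {
  stopifnot(is.data.frame(series), "maturation" %in% names(series), lo < hi)
  series[!(series$maturation > hi | series$maturation < lo), , drop = FALSE]
}

#' Stepwise deletion of the largest standardized residuals
#'
#' Iteratively fits the through-origin regression, standardizes residuals
#' internally (residual divided by the root-mean-square residual
#' sqrt(SSres/(n-1)) of the current fit; `type = "studentized"` switches
#' to leave-one-out externally studentized residuals), deletes the point
#' with the largest absolute standardized residual (ties broken by id
#' order), and refits. The trace records each removal and the R2 after it.
#' Because the removed points had the largest residuals, the reported
#' summary is the relative reduction in residual sum of squares between
#' the baseline fit and the final fit (in percent), alongside the plain
#' change in R2 -- both accountings of how much unexplained variance the
#' removed set carried.
#'
#' @param x,y Numeric vectors (early-stage and maturation fractions).
#' @param ids Point identifiers (plant ids); default 1..n.
#' @param n_steps Number of deletions, `0 <= n_steps < n - 1`.
#' @param type `"internal"` (default) or `"studentized"`.
#' @return Object of class `deletion_trace`: `trace` data.frame
#'   (removed_id, std_residual, r2_after), `baseline_r2`, `final_r2`,
#'   `ss_res_reduction_pct`, `delta_r2`, `kept_ids`.
#' @export
stepwise_residual_deletion <- function(x, y, ids = seq_along(x), n_steps,
                                       type = c("internal", "studentized")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y), length(ids) == length(x))
  n <- length(x)
  if (n_steps < 0 || n_steps >= n - 1) {
    stop(sprintf("n_steps must be in [0, %d)", n - 1L))
  }
  base <- regress_through_origin(x, y)
  keep <- seq_len(n)
  trace <- data.frame(removed_id = character(0), std_residual = numeric(0),
                      r2_after = numeric(0), stringsAsFactors = FALSE)
  fit <- base
  if (n_steps > 0) {
    for (step in seq_len(n_steps)) {
      m <- length(keep)
      r <- if (type == "internal") {
        s <- sqrt(fit$ss_res / (m - 1))
        fit$residuals / s
      } else {
        stats::rstudent(stats::lm(y[keep] ~ x[keep] + 0))
      }
      # largest |r|; ties broken by id order for reproducible traces
      ord <- order(-abs(r), as.character(ids[keep]))
      drop_local <- ord[1]
      removed <- keep[drop_local]
      keep <- keep[-drop_local]
      fit <- regress_through_origin(x[keep], y[keep])
      trace <- rbind(trace, data.frame(
        removed_id = as.character(ids[removed]),
        std_residual = unname(r[drop_local]),
        r2_after = fit$r_squared, stringsAsFactors = FALSE))
    }
  }
  structure(
    list(trace = trace,
         baseline_r2 = base$r_squared,
         final_r2 = fit$r_squared,
         ss_res_reduction_pct = if (base$ss_res > 0)
           100 * (base$ss_res - fit$ss_res) / base$ss_res else 0,
         delta_r2 = fit$r_squared - base$r_squared,
         kept_ids = as.character(ids[keep])),
    class = "deletion_trace"
  )
}

#' @export
print.deletion_trace <- function(x, ...) {
  cat(sprintf("Stepwise residual deletion: %d point(s) removed\n", nrow(x$trace)))
  if (nrow(x$trace) > 0) print(x$trace, row.names = FALSE)
  cat(sprintf("  baseline R2 %.4f -> final R2 %.4f (delta %.4f); residual SS reduced %.1f%%\n",
              x$baseline_r2, x$final_r2, x$delta_r2, x$ss_res_reduction_pct))
  invisible(x)
}

#' Wide per-plant stage series for one fraction statistic
#'
#' Pivots the long fraction table to one row per plant with the chosen
#' statistic at each developmental stage. Plants missing any stage are
#' excluded with a message (they cannot enter the stage regressions).
#'
#' @param fractions Long fraction table from [fractions_table()].
#' @param statistic `"F_dicyclic"` or `"F_C3"` (any fraction column).
#' @return data.frame with plant_id, accession, vegetative, flowering,
#'   maturation.
#' @export
stage_series <- function(fractions, statistic = c("F_dicyclic", "F_C3",
                                                  "F_C5", "F_tricyclic")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("plant_id", "stage", statistic) %in% names(fractions)))
  wide <- stats::reshape(
    fractions[, c("plant_id", "stage", statistic)],
    idvar = "plant_id", timevar = "stage", direction = "wide")
  names(wide) <- sub(paste0("^", statistic, "\\."), "", names(wide))
  stages <- c("vegetative", "flowering", "maturation")
  missing_stage <- setdiff(stages, names(wide))
  if (length(missing_stage) > 0L) {
    stop("stage(s) absent from fraction table: ", paste(missing_stage, collapse = ", "))
  }
  complete <- stats::complete.cases(wide[, stages])
  if (any(!complete)) {
    message(sum(!complete), " plant(s) excluded: incomplete stage series")
  }
  wide <- wide[complete, , drop = FALSE]
  if ("accession" %in% names(fractions)) {
    acc <- fractions[!duplicated(fractions$plant_id), c("plant_id", "accession")]
    wide <- merge(wide, acc, by = "plant_id", sort = TRUE)
  }
  rownames(wide) <- NULL
  wide[order(wide$plant_id), c("plant_id",
                               intersect("accession", names(wide)), stages)]
}

#' Developmental stability report
#'
#' The four through-origin regressions of maturation fractions on earlier
#' stages: (F_dicyclic, F_C3) x (vegetative, flowering). High R2 indicates
#' that chemotype at the early stage predicts chemotype at maturation,
#' i.e. low developmental plasticity.
#'
#' @param fractions Long fraction table from [fractions_table()].
#' @param statistics Fraction statistics to regress.
#' @return data.frame with one row per statistic x early stage: slope, R2,
#'   F, dfs, p, n.
#' @export
stage_stability_report <- function(fractions,
                                   statistics = c("F_dicyclic", "F_C3")) {
  rows <- list()
  for (stat in statistics) {
    wide <- stage_series(fractions, stat)
    if (nrow(wide) < 3L) stop("need at least 3 complete stage series")
    for (early in c("vegetative", "flowering")) {
      fit <- regress_through_origin(wide[[early]], wide$maturation)
      rows[[paste(stat, early)]] <- data.frame(
        statistic = stat, early_stage = early,
        slope = fit$slope, r_squared = fit$r_squared,
        f_statistic = fit$f_statistic, df1 = fit$df[1], df2 = fit$df[2],
        p_value = fit$p_value, n = fit$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
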
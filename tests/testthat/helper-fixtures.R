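# Shared fixture builders and independent oracles.

# calibration points on a known response, optionally with multiplicative noise
make_cal_points <- function(a = 0, b = 100, c0 = 0,
                            levels = c(0.032, 0.16, 0.8, 4, 20, 100),
                            rsd = 0, analyte = NULL) {
  mu <- a * levels^2 + b * levels + c0
  area <- mu * (1 + stats::rnorm(length(levels), 0, rsd))
  df <- data.frame(concentration_ug_ml = levels, peak_area = area)
  if (!is.null(analyte)) df$analyte <- analyte
  df
}

# brute-force 1-D least-squares oracle for the through-origin slope
grid_origin_slope <- function(x, y, lo = 0, hi = 5, n_grid = 200001) {
  s <- seq(lo, hi, length.out = n_grid)
  sse <- vapply(s, function(si) sum((y - si * x)^2), numeric(1))
  list(slope = s[which.min(sse)], sse = min(sse))
}

# exhaustive-partition oracle: global minimum WSS over all assignments of
# n points to at most k clusters (feasible only for tiny n)
exhaustive_kmeans_wss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 8, k <= 3)
  grids <- rep(list(seq_len(k)), n)
  assignments <- as.matrix(expand.grid(grids))
  best <- Inf
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    wss <- 0
    for (cl in unique(a)) {
      pts <- X[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# small deterministic fraction panel (truth only) for plasticity/cluster tests
make_truth_panel <- function(seed = 1, config = default_generator_config(seed)) {
  chemovar:::with_preserved_seed(config$seed, {
    g <- simulate_genotypes(config)
    list(genotypes = g, truth = simulate_fraction_truth(g, config))
  })
}
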
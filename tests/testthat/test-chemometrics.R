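test_that("k-means separates tight groups and is seed-reproducible", {
  pts <- rbind(matrix(rep(c(5, 5, 5), 10), ncol = 3, byrow = TRUE),
               matrix(rep(c(95, 95, 95), 10), ncol = 3, byrow = TRUE)) +
    matrix(stats::rnorm(60, 0, 0.5), ncol = 3)
  colnames(pts) <- c("vegetative", "flowering", "maturation")
  m <- chemotype_kmeans(pts, k = 2, seed = 4)
  expect_equal(unname(sort(rowMeans(m$centroids))), c(5, 95), tolerance = 0.5)
  expect_equal(length(unique(m$assignments[1:10])), 1L)
  expect_equal(length(unique(m$assignments[11:20])), 1L)
  m2 <- chemotype_kmeans(pts, k = 2, seed = 4)
  expect_identical(m$assignments, m2$assignments)
  expect_identical(m$wss, m2$wss)
  # k = n gives zero within-cluster scatter
  small <- pts[1:5, ]
  expect_equal(chemotype_kmeans(small, k = 5, seed = 1)$wss, 0, tolerance = 1e-9)
  expect_error(chemotype_kmeans(small, k = 6, seed = 1), "distinct")
})

test_that("k-means attains the exhaustive-partition optimum for tiny instances", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    X <- matrix(stats::runif(n * 3, 0, 100), ncol = 3)
    colnames(X) <- c("vegetative", "flowering", "maturation")
    m <- chemotype_kmeans(X, k = k, seed = i, restarts = 100)
    expect_equal(m$wss, exhaustive_kmeans_wss(X, k), tolerance = 1e-6)
  }
})

test_that("fitted WSS never exceeds random-assignment WSS", {
  set.seed(2)
  X <- matrix(stats::runif(60, 0, 100), ncol = 3)
  colnames(X) <- c("vegetative", "flowering", "maturation")
  m <- chemotype_kmeans(X, k = 3, seed = 8)
  for (i in 1:100) {
    a <- sample(1:3, nrow(X), replace = TRUE)
    wss <- sum(vapply(unique(a), function(cl) {
      pts <- X[a == cl, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    expect_lte(m$wss, wss + 1e-9)
  }
})

test_that("criterion curve is monotone and starts at the total scatter", {
  panel <- make_truth_panel(seed = 21)
  wide <- stage_series(panel$truth, "F_dicyclic")
  curve <- criterion_curve(wide, k_max = 6, seed = 3, restarts = 20)
  expect_equal(length(curve), 6L)
  expect_true(all(diff(curve) <= 1e-9))
  X <- as.matrix(wide[, c("vegetative", "flowering", "maturation")])
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  expect_equal(unname(curve[1]), tss, tolerance = 1e-9)

  # one tight cluster: the curve flattens immediately in relative terms
  tight <- matrix(stats::rnorm(90, 50, 0.5), ncol = 3)
  colnames(tight) <- c("vegetative", "flowering", "maturation")
  ct <- criterion_curve(tight, k_max = 4, seed = 1, restarts = 10)
  expect_lt(ct[1] / max(ct[2], 1e-12), 3)
})

test_that("elbow selection finds constructed elbows and flags flat curves", {
  curve <- c(`1` = 1000, `2` = 400, `3` = 100, `4` = 90, `5` = 85)
  sel <- select_k(curve)
  expect_equal(sel$k, 3L)
  expect_false(sel$low_confidence)
  lin <- c(`1` = 100, `2` = 80, `3` = 60, `4` = 40)
  sel_lin <- select_k(lin)
  expect_equal(sel_lin$k, 2L)
  expect_true(sel_lin$low_confidence)
  expect_error(select_k(c(`1` = 10, `2` = 5)), "at least 3")
})

test_that("the default panel structure yields a three-cluster elbow", {
  hits <- c(F_dicyclic = 0, F_C3 = 0)
  n_runs <- 20
  for (i in seq_len(n_runs)) {
    panel <- make_truth_panel(seed = 400 + i)
    for (stat in names(hits)) {
      wide <- stage_series(panel$truth, stat)
      curve <- criterion_curve(wide, k_max = 8, seed = i, restarts = 20)
      if (select_k(curve)$k == 3L) hits[[stat]] <- hits[[stat]] + 1
    }
  }
  expect_gte(hits[["F_dicyclic"]] / n_runs, 0.9)
  expect_gte(hits[["F_C3"]] / n_runs, 0.9)
})

test_that("class labelling orders clusters and reports maturation ranges", {
  set.seed(19)
  mk_group <- function(center, n) {
    m <- matrix(stats::rnorm(n * 3, center, 2), ncol = 3)
    colnames(m) <- c("vegetative", "flowering", "maturation")
    m
  }
  X <- rbind(mk_group(5, 8), mk_group(40, 8), mk_group(80, 8))
  m <- label_classes(chemotype_kmeans(X, k = 3, seed = 2))
  means <- rowMeans(m$centroids)
  expect_equal(m$class_labels[order(means)], c("low", "intermediate", "high"))
  for (i in 1:3) {
    v <- X[m$assignments == i, "maturation"]
    expect_equal(unname(m$class_ranges[[i]]), c(min(v), max(v)))
  }
  m2 <- label_classes(chemotype_kmeans(X, k = 2, seed = 2))
  expect_setequal(m2$class_labels, c("class_1", "class_2"))
})

test_that("overlapping latent classes can produce overlapping reported ranges", {
  panel <- make_truth_panel(seed = 33)
  wide <- stage_series(panel$truth, "F_C3")
  m <- label_classes(chemotype_kmeans(wide, k = 3, seed = 3))
  ord <- order(rowMeans(m$centroids))
  r <- m$class_ranges
  # adjacent class ranges may touch or overlap (as latent classes overlap);
  # they must at least be ordered by their midpoints
  mids <- vapply(r, mean, numeric(1))
  expect_equal(order(mids), ord)
})
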
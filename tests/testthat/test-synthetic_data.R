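test_that("the default panel matches the published study dimensions", {
  plan <- default_accession_plan()
  expect_equal(nrow(plan), 20L)
  expect_equal(sum(plan$n_plants), 99L)
  expect_true(all(plan$n_plants >= 3 & plan$n_plants <= 7))
  panel <- simulate_panel(default_generator_config(seed = 2))
  expect_equal(nrow(panel$genotypes), 99L)
  expect_equal(length(unique(panel$genotypes$accession)), 20L)
  # 99 plants x 3 stages x 2 replicates x 12 analytes of peak areas
  expect_equal(nrow(panel$samples), 99L * 3L * 2L * 12L)
  expect_equal(nrow(panel$standards), 12L * 6L)
})

test_that("the generator is deterministic given a seed", {
  p1 <- simulate_panel(default_generator_config(seed = 9))
  p2 <- simulate_panel(default_generator_config(seed = 9))
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$standards, p2$standards)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_panel(default_generator_config(seed = 10))
  expect_false(identical(p1$samples$peak_area, p3$samples$peak_area))
})

test_that("latent genotype draws respect their class supports", {
  g <- chemovar:::with_preserved_seed(4, simulate_genotypes())
  rng <- list(homozygous_tricyclic = c(0.5, 7), heterozygous = c(25, 75),
              homozygous_dicyclic = c(93, 99.5))
  for (b in names(rng)) {
    v <- g$latent_F_dicyclic[g$b_locus == b]
    expect_true(all(v >= rng[[b]][1] & v <= rng[[b]][2]))
  }
  crng <- list(low = c(0.4, 20), intermediate = c(18, 65), high = c(60, 92))
  for (cl in names(crng)) {
    v <- g$latent_F_C3[g$c3_class == cl]
    expect_true(all(v >= crng[[cl]][1] & v <= crng[[cl]][2]))
  }
  expect_equal(sum(g$is_outlier), 3L)
  expect_true(all(g$b_locus[g$is_outlier] == "heterozygous"))
})

test_that("fraction decomposition round-trips targets exactly", {
  set.seed(14)
  for (i in 1:50) {
    f_c3 <- stats::runif(1, 0, 100)
    f_di <- stats::runif(1, 0, 100)
    total <- stats::runif(1, 5, 200)
    s <- stats::runif(1, 0.3, 3)
    conc <- decompose_fractions(f_c3, f_di, total, het_skew = s)
    expect_true(all(conc >= 0))
    fr <- compute_fractions(conc)
    expect_equal(fr$F_C3, f_c3, tolerance = 1e-9)
    expect_equal(fr$F_dicyclic, f_di, tolerance = 1e-9)
    expect_equal(fr$total, total, tolerance = 1e-9)
    # configured within-class skew is reproduced where both pools exist
    w <- within_class_ratios(conc)
    if (!w$undefined && all(conc[c("THCVA", "CBDVA")] > 1e-9)) {
      expect_equal(w$het_ratio, s, tolerance = 1e-6)
    }
  }
})

test_that("decomposition handles degenerate corners", {
  pure <- decompose_fractions(0, 100, 10)
  expect_equal(unname(pure[["CBDA"]] + pure[["CBD"]] * 0 + 0), unname(pure[["CBDA"]]))
  fr <- suppressWarnings(compute_fractions(pure))
  expect_equal(fr$F_dicyclic, 100)
  expect_equal(fr$F_C3, 0)
  all_c3 <- decompose_fractions(100, 0, 10, het_skew = 1.44)
  fr2 <- compute_fractions(all_c3)
  expect_equal(fr2$F_C3, 100)
  expect_equal(fr2$F_tricyclic, 100)
})

test_that("heterozygote cohort recovers the configured dicyclic skew", {
  panel <- simulate_panel(default_generator_config(seed = 16))
  mat <- panel$truth[panel$truth$stage == "maturation", ]
  het <- mat[mat$plant_id %in%
               panel$genotypes$plant_id[panel$genotypes$b_locus == "heterozygous"], ]
  ratios <- vapply(seq_len(nrow(het)), function(i) {
    conc <- stats::setNames(as.numeric(het[i, fraction_analytes()]),
                            fraction_analytes())
    within_class_ratios(conc)$het_ratio
  }, numeric(1))
  expect_equal(mean(ratios, na.rm = TRUE), 1.44, tolerance = 1e-6)
})

test_that("all three B-locus modes are occupied under default weights", {
  panel <- simulate_panel(default_generator_config(seed = 8))
  counts <- trimodality_check(panel$truth)
  expect_equal(length(counts), 3L)
  expect_true(all(counts > 0))
  expect_equal(sum(counts), 99L)
})

test_that("degenerate and balanced mixtures shape the modes as expected", {
  cfg <- default_generator_config(seed = 12)
  cfg$b_locus_weights <- c(homozygous_tricyclic = 0, heterozygous = 0,
                           homozygous_dicyclic = 1)
  mono <- make_truth_panel(config = cfg)
  counts <- trimodality_check(mono$truth)
  expect_equal(unname(counts[["homozygous_dicyclic"]]), 99L)
  expect_equal(sum(counts), 99L)

  cfg2 <- default_generator_config(seed = 13)
  cfg2$b_locus_weights <- c(homozygous_tricyclic = 1 / 3, heterozygous = 1 / 3,
                            homozygous_dicyclic = 1 / 3)
  bal <- make_truth_panel(config = cfg2)
  counts2 <- trimodality_check(bal$truth)
  # binomial(99, 1/3) 99% interval around 33
  expect_true(all(counts2 >= stats::qbinom(0.005, 99, 1 / 3) &
                    counts2 <= stats::qbinom(0.995, 99, 1 / 3)))
})

test_that("planted outliers drift toward parity only at later stages", {
  panel <- simulate_panel(default_generator_config(seed = 20))
  out_ids <- panel$genotypes$plant_id[panel$genotypes$is_outlier]
  tr <- panel$truth[panel$truth$plant_id %in% out_ids, ]
  for (id in out_ids) {
    lat <- panel$genotypes$latent_F_dicyclic[panel$genotypes$plant_id == id]
    veg <- tr$F_dicyclic[tr$plant_id == id & tr$stage == "vegetative"]
    mat <- tr$F_dicyclic[tr$plant_id == id & tr$stage == "maturation"]
    expect_lt(abs(veg - lat), 6)  # vegetative stays near the latent value
    # the 25 pp drift spans the whole heterozygous band, so maturation sits
    # at parity up to stage noise
    expect_lt(abs(mat - 50), 6)
  }
})
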
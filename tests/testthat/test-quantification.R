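test_that("calibration fitting recovers exact linear and quadratic responses", {
  lin <- fit_calibration(make_cal_points(a = 0, b = 100))
  expect_equal(unname(lin$coefficients), c(0, 100, 0), tolerance = 1e-8)
  expect_equal(lin$r2_linear, 1, tolerance = 1e-12)
  expect_equal(lin$valid_range, c(0.032, 100))

  quad <- fit_calibration(make_cal_points(a = 1, b = 50))
  expect_equal(unname(quad$coefficients), c(1, 50, 0), tolerance = 1e-8)
})

test_that("calibration fitting rejects unusable input", {
  expect_error(fit_calibration(make_cal_points(levels = c(1, 2))), "3 distinct")
  # steeply decreasing response: not invertible
  bad <- data.frame(concentration_ug_ml = c(1, 10, 100),
                    peak_area = c(1000, 100, 10))
  expect_error(fit_calibration(bad), "not strictly increasing")
  expect_error(
    fit_calibration(data.frame(concentration_ug_ml = 1:6, peak_area = 1:6,
                               analyte = rep(c("THC", "CBD"), 3))),
    "mix analytes")
})

test_that("2% detector noise keeps the linearity diagnostic above 0.99", {
  set.seed(101)
  r2 <- replicate(1000, fit_calibration(make_cal_points(rsd = 0.02))$r2_linear)
  expect_gte(median(r2), 0.99)
})

test_that("inversion solves linear and factorable quadratic cases", {
  lin <- fit_calibration(make_cal_points(a = 0, b = 100))
  expect_equal(as.numeric(invert_calibration(400, lin)), 4, tolerance = 1e-6)
  quad <- fit_calibration(make_cal_points(a = 1, b = 50))
  # 104 = x^2 + 50x at x = 2
  expect_equal(as.numeric(invert_calibration(104, quad)), 2, tolerance = 1e-6)
})

test_that("inversion round-trips random monotone curves to 1e-9 relative", {
  set.seed(7)
  for (i in 1:1000) {
    a <- stats::runif(1, 0, 2)
    b <- stats::runif(1, 50, 2000)
    c0 <- stats::runif(1, -5, 5)
    curve <- structure(list(analyte = "X", coefficients = c(a = a, b = b, c = c0),
                            valid_range = c(0.032, 100), r2_linear = 1,
                            fit_date = NA), class = "calibration_curve")
    conc <- stats::runif(1, 0.05, 100)
    area <- a * conc^2 + b * conc + c0
    expect_equal(as.numeric(invert_calibration(area, curve)), conc,
                 tolerance = 1e-9)
  }
})

test_that("inversion flags sub-LOQ values and errors on saturation", {
  lin <- fit_calibration(make_cal_points(a = 0, b = 100))
  x <- invert_calibration(1, lin)  # 0.01 ug/mL, below the 0.032 standard
  expect_equal(as.numeric(x), 0.01, tolerance = 1e-6)
  expect_true(attr(x, "below_loq"))
  expect_false(attr(invert_calibration(400, lin), "below_loq"))
  expect_error(invert_calibration(2e4, lin), "saturation")
  expect_error(invert_calibration(-1, lin), ">= 0")
})

test_that("sample quantification back-corrects dilution and converts units", {
  lin <- fit_calibration(make_cal_points(a = 0, b = 100), analyte = "THCA")
  prof <- quantify_sample(
    c(THCA = 400), list(THCA = lin),
    list(plant_id = "A01", stage = "maturation", dilution_factor = 5,
         tissue_mass_mg = 250, solvent_volume_ml = 25))
  expect_equal(unname(prof$concentrations[["THCA"]]), 20, tolerance = 1e-6)
  expect_equal(unname(prof$mg_per_g[["THCA"]]), 2, tolerance = 1e-6)
  # homogeneous in dilution: doubling the dilution doubles concentrations
  prof10 <- quantify_sample(c(THCA = 400), list(THCA = lin),
                            list(plant_id = "A01", stage = "maturation",
                                 dilution_factor = 10))
  expect_equal(prof10$concentrations[["THCA"]],
               2 * prof$concentrations[["THCA"]], tolerance = 1e-9)
  expect_error(
    quantify_sample(c(CBD = 1), list(THCA = lin),
                    list(plant_id = "A01", stage = "maturation")),
    "CBD")
})

test_that("replicate merging averages, commutes, and is idempotent on identicals", {
  mk <- function(vals, rep_i) structure(
    list(plant_id = "A01", accession = "A", stage = "maturation",
         replicate = rep_i, concentrations = vals),
    class = "cannabinoid_profile")
  r1 <- mk(c(THCA = 10, CBDA = 4), 1)
  r2 <- mk(c(THCA = 20, CBDA = 4), 2)
  m12 <- merge_replicates(r1, r2)
  expect_equal(m12$concentrations[["THCA"]], 15)
  expect_equal(m12$concentrations[["CBDA"]], 4)
  m21 <- merge_replicates(r2, r1)
  expect_equal(m12$concentrations, m21$concentrations[names(m12$concentrations)])
  same <- merge_replicates(r1, mk(c(THCA = 10, CBDA = 4), 2))
  expect_equal(same$concentrations, r1$concentrations)
  bad <- mk(c(THCA = 1), 2); bad$plant_id <- "B01"
  expect_error(merge_replicates(r1, bad), "disagree")
})

test_that("averaging duplicate replicates usually beats a single replicate", {
  # variance reduction: for iid 2% errors the mean is closer to truth than a
  # given single replicate with probability atan-derived ~0.648
  set.seed(11)
  wins <- replicate(1000, {
    truth <- 10
    r1 <- truth * (1 + rnorm(1, 0, 0.02))
    r2 <- truth * (1 + rnorm(1, 0, 0.02))
    abs((r1 + r2) / 2 - truth) < abs(r1 - truth)
  })
  expect_gte(mean(wins), 0.6)
})

test_that("repeatability R2 is 1 for identical pairs and ~0 for shuffled pairs", {
  set.seed(5)
  f <- data.frame(F_C3 = runif(99, 0, 90), F_C5 = NA, F_dicyclic = runif(99, 0, 100))
  f$F_C5 <- 100 - f$F_C3
  f$F_tricyclic <- 100 - f$F_dicyclic
  r2 <- replicate_repeatability(f, f)
  expect_equal(unname(r2), rep(1, 4), tolerance = 1e-12)
  shuf <- f[sample(nrow(f)), ]
  expect_lt(replicate_repeatability(f, shuf)[["F_C3"]], 0.1)
  expect_error(replicate_repeatability(f[1:2, ], f[1:2, ]), "at least 3")
  const <- f; const$F_C3 <- 50; const$F_C5 <- 50
  expect_error(replicate_repeatability(const, const), "constant")
})
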
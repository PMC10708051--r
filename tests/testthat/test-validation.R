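fit_quiet <- function(...) suppressWarnings(fit_calibration(...))

test_that("calibration fit recovers noiseless coefficients exactly", {
  plate <- make_calibration_plate(c(5, 20, 40, 80, 120), 3,
                                  slope = 0.0289, intercept = 0.0887)
  fit <- fit_quiet(plate$nominal_ug_ml, plate$absorbance)
  expect_equal(fit$slope, 0.0289, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.0887, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$conc_range, c(5, 120))

  # identity line
  f2 <- fit_quiet(1:5, 1:5)
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 2, 3, 4), c(1, 2, 3, 4)), "5 unique")
  expect_error(fit_calibration(rep(3, 6), rnorm(6)), "5 unique")
})

test_that("noisy calibration coefficients fall within 3 SE of truth ~95% of the time", {
  levels <- c(5, 20, 40, 80, 120)
  ok <- vapply(1:200, function(s) {
    plate <- make_calibration_plate(levels, 3, slope = 0.0289,
                                    intercept = 0.0887,
                                    noise = noise_model(0.005, 0, seed = s))
    fit <- fit_calibration(plate$nominal_ug_ml, plate$absorbance)
    se <- tidy(fit)$std.error
    abs(fit$intercept - 0.0887) < 3 * se[1] && abs(fit$slope - 0.0289) < 3 * se[2]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("LOD/LOQ follow the ICH formulas and their fixed ratio", {
  fit <- structure(
    list(slope = 0.1, intercept = 0.05, intercept_se = 0.01,
         r_squared = 0.999, n = 15, conc_range = c(1, 100)),
    class = "calibration_fit"
  )
  ll <- lod_loq(fit)
  expect_equal(ll$lod, 0.33)
  expect_equal(ll$loq, 1.00)
  expect_equal(ll$loq / ll$lod, 10 / 3.3)

  # inversion against a known LOD: SDa = LOD * b / 3.3
  fit$slope <- 0.0289
  fit$intercept_se <- 0.0289 * 2.5 / 3.3
  expect_equal(lod_loq(fit)$lod, 2.5)

  fit$slope <- -1
  expect_error(lod_loq(fit), "positive")
})

test_that("LOD/LOQ scale inversely with slope and linearly with intercept SE", {
  base <- structure(
    list(slope = 0.05, intercept = 0.1, intercept_se = 0.004,
         r_squared = 0.999, n = 15, conc_range = c(1, 100)),
    class = "calibration_fit"
  )
  double_se <- base; double_se$intercept_se <- 0.008
  double_slope <- base; double_slope$slope <- 0.1
  expect_equal(lod_loq(double_se)$lod, 2 * lod_loq(base)$lod)
  expect_equal(lod_loq(double_slope)$lod, lod_loq(base)$lod / 2)
})

test_that("precision/accuracy summaries obey the recovery-error identity", {
  exact <- precision_accuracy(rep(60, 3), 60)
  expect_equal(exact$recovery_pct, 100)
  expect_equal(exact$error_pct, 0)
  expect_equal(exact$rsd_pct, 0)

  # a 99.6% recovery at nominal 60 must report error -0.4
  found <- c(59.5, 59.9, 59.88)  # mean 59.76 -> 99.6%
  pa <- precision_accuracy(found, 60)
  expect_equal(pa$recovery_pct, 99.6)
  expect_equal(pa$error_pct, -0.4)

  # identity across random inputs
  set.seed(3)
  for (i in 1:20) {
    f <- runif(5, 50, 70)
    pa <- precision_accuracy(f, 60)
    expect_equal(pa$error_pct, pa$recovery_pct - 100)
  }
  expect_error(precision_accuracy(c(1, 2), 0), "positive")
  expect_error(precision_accuracy(60, 60), "2 replicates")
})

test_that("replicate RSD stays at or below 2% in at least 90% of seeded runs", {
  ok <- vapply(1:200, function(s) {
    plate <- make_calibration_plate(c(20, 60, 100), 3, slope = 0.0289,
                                    intercept = 0.0887,
                                    noise = noise_model(0.002, 0.005, seed = s))
    found <- (plate$absorbance - 0.0887) / 0.0289
    rsd <- vapply(split(found, plate$nominal_ug_ml),
                  function(f) precision_accuracy(f, mean(f))$rsd_pct, numeric(1))
    all(rsd <= 2)
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("quantitation inverts calibration on noiseless plates", {
  std <- make_calibration_plate(c(5, 20, 40, 80, 120), 2,
                                slope = 0.0289, intercept = 0.0887)
  unk_conc <- c(15, 50, 110)
  unk <- tibble::tibble(
    well = paste0("H", 1:3),
    sample_id = paste0("unk", 1:3),
    nominal_ug_ml = unk_conc,
    role = "unknown",
    absorbance = 0.0887 + 0.0289 * unk_conc
  )
  layout <- dplyr::bind_rows(
    std[, c("well", "sample_id", "nominal_ug_ml", "role")],
    unk[, c("well", "sample_id", "nominal_ug_ml", "role")]
  )
  readings <- dplyr::bind_rows(std[, c("well", "absorbance")],
                               unk[, c("well", "absorbance")])
  fit <- fit_quiet(std$nominal_ug_ml, std$absorbance)
  out <- quantify_unknowns(fit, readings, layout)
  got <- out[out$role == "unknown", ]
  expect_equal(got$found_ug_ml, unk_conc, tolerance = 1e-6)
  expect_true(all(got$in_range))

  # a single exact inversion
  one <- quantify_unknowns(
    fit,
    tibble::tibble(well = "H4", absorbance = 0.0887 + 0.0289 * 50),
    tibble::tibble(well = "H4", sample_id = "x", nominal_ug_ml = NA_real_,
                   role = "unknown")
  )
  expect_equal(one$found_ug_ml, 50, tolerance = 1e-9)

  # below-intercept reading: negative concentration, flagged out of range
  low <- quantify_unknowns(
    fit,
    tibble::tibble(well = "H5", absorbance = 0.01),
    tibble::tibble(well = "H5", sample_id = "low", nominal_ug_ml = NA_real_,
                   role = "unknown")
  )
  expect_lt(low$found_ug_ml, 0)
  expect_false(low$in_range)

  expect_error(
    quantify_unknowns(fit, tibble::tibble(well = "H6", absorbance = 1), layout),
    "H6"
  )
})

test_that("label claim, robustness summary and throughput arithmetic", {
  expect_equal(label_claim(60, 60), 100)
  expect_equal(label_claim(50.4, 50), 100.8)
  expect_error(label_claim(50, 0), "positive")

  expect_equal(throughput(5, 96, 6), 2880)
  expect_error(throughput(0, 96, 6), "positive")

  runs <- tibble::tibble(
    condition = rep(c("reagent_0.8pct", "reagent_1.2pct"), each = 3),
    nominal_ug_ml = 60,
    found_ug_ml = c(59.1, 60.2, 59.8, 60.4, 61.0, 60.1)
  )
  summ <- robustness_summary(runs)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$recovery_pct[1], 100 * mean(c(59.1, 60.2, 59.8)) / 60)
  expect_equal(summ$error_pct, summ$recovery_pct - 100)
})

test_that("grouped seeded runs at two reagent levels keep RSD within the noise bound", {
  # absolute 0.002 + relative 0.5% on absorbances ~1.8 AU maps to found-conc
  # RSDs well under 1%; 2% is a loose ceiling for the summary check
  runs <- purrr::map_dfr(1:2, function(g) {
    plate <- make_calibration_plate(rep(60, 3), 1, slope = 0.0289,
                                    intercept = 0.0887,
                                    noise = noise_model(0.002, 0.005, seed = g))
    tibble::tibble(
      condition = paste0("level", g),
      nominal_ug_ml = 60,
      found_ug_ml = (plate$absorbance - 0.0887) / 0.0289
    )
  })
  summ <- robustness_summary(runs)
  expect_true(all(summ$rsd_pct < 2))
})

test_that("plate CSV I/O round-trips and validates", {
  plate <- make_calibration_plate(c(5, 20, 40, 80, 120), 3,
                                  slope = 0.0289, intercept = 0.0887,
                                  noise = noise_model(0.002, 0.005, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate[, c("well", "absorbance")], path)
  back <- read_plate_csv(path)
  merged <- dplyr::inner_join(plate, back, by = "well",
                              suffix = c("", ".read"))
  expect_equal(nrow(merged), nrow(plate))
  expect_equal(merged$absorbance.read, merged$absorbance, tolerance = 1e-9)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_plate_csv(empty), "plate")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,1,2", "Z,0.1,0.2"), bad)
  expect_error(read_plate_csv(bad), "row label")
})

test_that("blank wells are subtracted before calibration when present", {
  std <- make_calibration_plate(c(5, 20, 40, 80, 120), 2,
                                slope = 0.0289, intercept = 0)
  plate <- dplyr::bind_rows(
    dplyr::mutate(std, absorbance = absorbance + 0.05),
    tibble::tibble(well = c("H11", "H12"), plate_row = "H",
                   plate_col = c(11, 12), sample_id = "blank",
                   nominal_ug_ml = 0, role = "blank", absorbance = 0.05)
  )
  fit <- suppressWarnings(calibration_from_plate(plate))
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$slope, 0.0289, tolerance = 1e-9)
})
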
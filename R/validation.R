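#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of absorbance on nominal concentration across
#' the standards, the ICH Q2 linearity model. When blank wells are present
#' (role `"blank"` in a plate tibble) their mean absorbance is subtracted
#' before fitting via [calibration_from_plate()]; this function takes the
#' already-paired vectors.
#'
#' @param concs Nominal concentrations, ug/mL; at least 5 unique levels.
#' @param absorbances Measured absorbances, AU; same length.
#' @return A `calibration_fit` with `slope` (AU per ug/mL), `intercept` (AU),
#'   `r_squared`, `intercept_se` (the OLS standard error of the intercept,
#'   the "SDa" used for LOD/LOQ), `n`, `conc_range`. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
#' @examples
#' plate <- make_calibration_plate(c(5, 20, 40, 80, 120), 3,
#'                                 slope = 0.0289, intercept = 0.0887)
#' fit_calibration(plate$nominal_ug_ml, plate$absorbance)
fit_calibration <- function(concs, absorbances) {
  if (length(concs) != length(absorbances)) {
    abort("concs and absorbances must have the same length")
  }
  if (length(unique(concs)) < 5) {
    abort("calibration needs at least 5 unique concentration levels")
  }
  if (sd(concs) == 0) abort("concentrations have zero variance")
  d <- tibble::tibble(conc = concs, absorbance = absorbances)
  fit <- lm(absorbance ~ conc, data = d)
  s <- summary(fit)
  structure(
    list(
      slope = coef(fit)[[2]],
      intercept = coef(fit)[[1]],
      r_squared = s$r.squared,
      intercept_se = s$coefficients["(Intercept)", "Std. Error"],
      n = nrow(d),
      conc_range = range(concs),
      data = d,
      lm = fit
    ),
    class = "calibration_fit"
  )
}

#' Fit a calibration from a plate tibble
#'
#' Convenience wrapper: rows with role `"standard"` feed [fit_calibration()];
#' if blank wells (role `"blank"`) exist, their mean absorbance is subtracted
#' from every standard first.
#'
#' @param plate Plate tibble with columns `nominal_ug_ml`, `role`,
#'   `absorbance`.
#' @return A `calibration_fit`.
#' @export
calibration_from_plate <- function(plate) {
  plate <- tibble::as_tibble(plate)
  std <- dplyr::filter(plate, .data$role == "standard")
  if (nrow(std) == 0) abort("plate contains no standard wells")
  blank <- dplyr::filter(plate, .data$role == "blank")
  y <- std$absorbance
  if (nrow(blank) > 0) y <- y - mean(blank$absorbance)
  fit_calibration(std$nominal_ug_ml, y)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: A = %.4f + %.4f C  (n = %d, R^2 = %.4f)\n",
              x$intercept, x$slope, x$n, x$r_squared))
  cat(sprintf("  range %g-%g ug/mL, SE(intercept) = %.3g AU\n",
              x$conc_range[1], x$conc_range[2], x$intercept_se))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"]
  )
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  ll <- lod_loq(x)
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, intercept_se = x$intercept_se,
                 lod = ll$lod, loq = ll$loq, nobs = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = expression("Concentration (" * mu * "g/mL)"),
                  y = "Absorbance (AU)",
                  title = sprintf("Calibration: R^2 = %.4f", object$r_squared))
}

#' Detection and quantitation limits
#'
#' ICH formulas LOD = 3.3 SDa / b and LOQ = 10 SDa / b, with SDa the standard
#' error of the calibration intercept and b the slope. LOQ/LOD is 10/3.3 by
#' construction.
#'
#' @param fit A `calibration_fit`.
#' @return Tibble with columns `lod`, `loq` (ug/mL).
#' @export
lod_loq <- function(fit) {
  if (!inherits(fit, "calibration_fit")) abort("fit must be a calibration_fit")
  if (fit$slope <= 0) abort("LOD/LOQ require a positive calibration slope")
  tibble::tibble(
    lod = 3.3 * fit$intercept_se / fit$slope,
    loq = 10 * fit$intercept_se / fit$slope
  )
}

#' Precision and accuracy of replicate determinations
#'
#' Standard assay summary: recovery = 100 * mean(found) / nominal (%),
#' error = recovery - 100 (%), RSD = 100 * sd(found) / mean(found) (%), with
#' the sample (n-1) standard deviation appropriate for the small replicate
#' counts of validation runs.
#'
#' @param found Replicate found concentrations, ug/mL; at least 2.
#' @param nominal Nominal concentration, ug/mL (> 0).
#' @return One-row tibble with `nominal`, `n`, `recovery_pct`, `error_pct`,
#'   `rsd_pct`.
#' @export
#' @examples
#' precision_accuracy(c(59.8, 60.3, 59.5), 60)
precision_accuracy <- function(found, nominal) {
  if (nominal <= 0) abort("nominal concentration must be positive")
  if (length(found) < 2) abort("at least 2 replicates are required")
  m <- mean(found)
  recovery <- 100 * m / nominal
  tibble::tibble(
    nominal = nominal,
    n = length(found),
    recovery_pct = recovery,
    error_pct = recovery - 100,
    rsd_pct = 100 * sd(found) / m
  )
}

#' Quantify unknown wells against a calibration
#'
#' C = (A - intercept) / slope for each read well; results outside the
#' calibration range are flagged (`in_range = FALSE`), never clipped, so
#' extrapolated values remain visible to the analyst.
#'
#' @param fit A `calibration_fit`.
#' @param readings Tibble with columns `well`, `absorbance`.
#' @param layout Tibble with columns `well`, `sample_id`, `nominal_ug_ml`,
#'   `role`; every read well must appear.
#' @return Tibble with `well`, `sample_id`, `role`, `nominal_ug_ml`,
#'   `absorbance`, `found_ug_ml`, `in_range`.
#' @export
quantify_unknowns <- function(fit, readings, layout) {
  if (!inherits(fit, "calibration_fit")) abort("fit must be a calibration_fit")
  readings <- tibble::as_tibble(readings)
  layout <- tibble::as_tibble(layout)
  missing_wells <- setdiff(readings$well, layout$well)
  if (length(missing_wells) > 0) {
    abort(sprintf("no layout entry for read well(s): %s",
                  paste(missing_wells, collapse = ", ")))
  }
  out <- dplyr::inner_join(readings, layout, by = "well")
  out <- dplyr::mutate(
    out,
    found_ug_ml = (.data$absorbance - fit$intercept) / fit$slope,
    in_range = .data$found_ug_ml >= fit$conc_range[1] &
      .data$found_ug_ml <= fit$conc_range[2]
  )
  dplyr::select(out, dplyr::any_of(c(
    "well", "sample_id", "role", "nominal_ug_ml", "absorbance",
    "found_ug_ml", "in_range"
  )))
}

#' Label claim of a formulation sample
#'
#' 100 * found / nominal (%), the percentage of the declared content actually
#' found.
#'
#' @param found Found concentration(s), ug/mL (> 0 nominal required).
#' @param nominal Nominal (declared) concentration, ug/mL (> 0).
#' @return Label claim percentage(s).
#' @export
#' @examples
#' label_claim(50.4, 50)  # 100.8 %
label_claim <- function(found, nominal) {
  if (any(nominal <= 0)) abort("nominal concentration must be positive")
  100 * found / nominal
}

#' Summarize robustness runs by condition
#'
#' For grouped replicate determinations (one group per deliberately varied
#' condition), reports per-condition recovery and RSD.
#'
#' @param runs Tibble with columns `condition`, `found_ug_ml`, `nominal_ug_ml`.
#' @return Tibble with one row per condition: `condition`, `n`,
#'   `recovery_pct`, `error_pct`, `rsd_pct`.
#' @export
robustness_summary <- function(runs) {
  runs <- tibble::as_tibble(runs)
  need <- c("condition", "found_ug_ml", "nominal_ug_ml")
  if (!all(need %in% names(runs))) {
    abort(sprintf("runs needs columns %s", paste(need, collapse = ", ")))
  }
  runs |>
    dplyr::group_by(.data$condition) |>
    dplyr::reframe(
      precision_accuracy(.data$found_ug_ml, unique(.data$nominal_ug_ml))
    ) |>
    dplyr::select(-"nominal")
}

#' Assay throughput
#'
#' Samples processed per hour: plates per batch x wells per plate x analysis
#' rounds per hour.
#'
#' @param plates_per_batch Number of plates handled simultaneously.
#' @param wells Wells per plate.
#' @param rounds_per_hour Analysis rounds per hour.
#' @return Samples per hour.
#' @export
#' @examples
#' throughput(5, 96, 6)  # 2880
throughput <- function(plates_per_batch, wells, rounds_per_hour) {
  if (plates_per_batch <= 0 || wells <= 0 || rounds_per_hour <= 0) {
    abort("all throughput arguments must be positive")
  }
  plates_per_batch * wells * rounds_per_hour
}

#' Read a 96-well plate readings CSV
#'
#' Format: 8 rows labelled A-H, 12 numeric columns labelled 1-12; the first
#' column holds the row labels. Empty cells are allowed (unused wells).
#'
#' @param path Path to the CSV.
#' @return Tibble with columns `well`, `absorbance` (empty wells dropped).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("plate file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("%s: not a plate file (need row labels A-H plus columns 1-12)", path))
  }
  row_lab <- raw[[1]]
  if (!all(row_lab %in% LETTERS[1:8])) {
    bad <- row_lab[!row_lab %in% LETTERS[1:8]][1]
    abort(sprintf("%s: invalid plate row label '%s'", path, bad))
  }
  long <- tidyr::pivot_longer(raw, -1, names_to = "plate_col", values_to = "absorbance")
  names(long)[1] <- "plate_row"
  long <- dplyr::filter(long, !is.na(.data$absorbance) & .data$absorbance != "")
  val <- suppressWarnings(as.numeric(long$absorbance))
  if (any(is.na(val))) {
    bad <- which(is.na(val))[1]
    abort(sprintf("%s: non-numeric absorbance in well %s%s", path,
                  long$plate_row[bad], long$plate_col[bad]))
  }
  tibble::tibble(
    well = paste0(long$plate_row, as.integer(long$plate_col)),
    absorbance = val
  )
}

#' Write plate-shaped absorbances to CSV
#'
#' Inverse of [read_plate_csv()]: an 8 x 12 grid with row labels A-H and
#' column headers 1-12; wells absent from `plate` are left empty.
#'
#' @param plate Tibble with columns `well`, `absorbance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  plate <- tibble::as_tibble(plate)
  grid <- matrix(NA_real_, 8, 12, dimnames = list(LETTERS[1:8], 1:12))
  r <- substr(plate$well, 1, 1)
  c <- as.integer(substring(plate$well, 2))
  if (any(!r %in% LETTERS[1:8]) || any(is.na(c)) || any(c < 1 | c > 12)) {
    abort("wells must lie within A1-H12")
  }
  if (anyDuplicated(plate$well)) abort("duplicate wells in plate")
  grid[cbind(match(r, LETTERS[1:8]), c)] <- plate$absorbance
  df <- tibble::as_tibble(as.data.frame(grid, check.names = FALSE))
  df <- dplyr::bind_cols(tibble::tibble(row = LETTERS[1:8]), df)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a plate layout CSV
#'
#' Format: columns `well`, `sample_id`, `nominal_ug_ml`, `role` with role in
#' standard/unknown/blank.
#'
#' @param path Path to the CSV.
#' @return Layout tibble.
#' @export
read_layout_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("layout file not found: %s", path))
  layout <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    sample_id = readr::col_character(),
    nominal_ug_ml = readr::col_double(),
    role = readr::col_character()
  ), show_col_types = FALSE)
  if (anyDuplicated(layout$well)) {
    abort(sprintf("%s: duplicate well '%s'", path, layout$well[duplicated(layout$well)][1]))
  }
  bad <- setdiff(unique(layout$role), c("standard", "unknown", "blank"))
  if (length(bad) > 0) {
    abort(sprintf("%s: unknown role '%s'", path, bad[1]))
  }
  layout
}
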
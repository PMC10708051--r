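#' Run configuration
#'
#' Bundles the physical and tuning parameters shared by the report-assembly
#' functions, so every report can embed the exact configuration it was
#' produced with. All physical values must be positive.
#'
#' @param temperature_K Temperature for free-energy calculations (default
#'   298 K).
#' @param path_cm Optical path length, cm (default 1; the effective microwell
#'   path depends on fill volume, so set it explicitly when it matters).
#' @param molar_mass Analyte molar mass, g/mol.
#' @param tauc_window_min_points,tauc_r2_min Tauc linear-region scan tuning.
#' @param prominence_frac Band-detection prominence threshold.
#' @param seed Integer seed routing all randomness in [ctc_simulate()].
#' @return A `run_config` list.
#' @export
run_config <- function(temperature_K = 298, path_cm = 1, molar_mass = 306.37,
                       tauc_window_min_points = 5, tauc_r2_min = 0.99,
                       prominence_frac = 0.05, seed = 1L) {
  vals <- c(temperature_K, path_cm, molar_mass, tauc_window_min_points,
            tauc_r2_min, prominence_frac)
  if (any(vals <= 0)) abort("all run_config physical values must be positive")
  structure(
    list(temperature_K = temperature_K, path_cm = path_cm,
         molar_mass = molar_mass,
         tauc_window_min_points = tauc_window_min_points,
         tauc_r2_min = tauc_r2_min, prominence_frac = prominence_frac,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

read_scenario <- function(scenario) {
  if (scenario %in% c("cla", "ddq")) {
    path <- system.file("extdata", paste0("scenario_", scenario, ".yaml"),
                        package = "ctcassay")
  } else {
    path <- scenario
  }
  if (!file.exists(path)) {
    abort(sprintf("unknown scenario '%s' (use 'cla', 'ddq' or a YAML path)", scenario))
  }
  yaml::read_yaml(path)
}

#' Simulate a full scenario to disk
#'
#' Generates, from a named scenario's ground-truth parameters, every input
#' the downstream stages consume: a reaction spectrum CSV, a donor titration
#' CSV (Benesi-Hildebrand-exact mode), a Job's series CSV, a Tauc absorption
#' edge CSV and a calibration plate CSV with its layout, plus a JSON sidecar
#' echoing the ground truth. Deterministic given (scenario, config).
#'
#' @param scenario `"cla"`, `"ddq"`, or a path to a scenario YAML file.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()]; its `seed` drives all noise.
#' @param noisy If `FALSE` (default) outputs are noiseless; if `TRUE` the
#'   default plate/spectrum noise model is applied.
#' @return Invisibly, a named list of the file paths written.
#' @export
ctc_simulate <- function(scenario, out_dir, config = run_config(), noisy = FALSE) {
  sc <- read_scenario(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nm <- function(f) file.path(out_dir, f)
  noise <- if (noisy) noise_model(0.002, 0.005, seed = config$seed) else noise_model(0, 0)

  # reaction spectrum: CT band on top of the donor's UV bands
  bands <- dplyr::bind_rows(
    purrr::map(sc$donor_uv_peaks_nm, ~ band_spec(.x, 8, 0.6)),
    band_spec(sc$lambda_max_nm, 25, 0.8)
  )
  spectrum <- make_spectrum(bands, seq(200, 700, by = 0.5), noise)
  write_spectrum_csv(spectrum, nm("reaction_spectrum.csv"))

  titration <- make_titration(
    seq(sc$donor_conc_range_M[1], sc$donor_conc_range_M[2], length.out = 6),
    sc$acceptor_conc_M, K = sc$K_L_mol, epsilon = sc$epsilon_L_mol_cm,
    path = config$path_cm, noise = noise, mode = "bh_exact"
  )
  readr::write_csv(titration, nm("titration.csv"))

  job <- make_job_series(2e-3, sc$K_L_mol, sc$epsilon_L_mol_cm,
                         seq(0.1, 0.9, by = 0.1), path = config$path_cm,
                         noise = noise)
  readr::write_csv(job, nm("job_series.csv"))

  edge <- make_tauc_edge(sc$band_gap_eV, B = 1,
                         energies = seq(1.5, 3.5, by = 0.01), noise = noise)
  readr::write_csv(edge, nm("tauc_edge.csv"))

  levels <- seq(sc$calibration$linear_range_ug_ml[1],
                sc$calibration$linear_range_ug_ml[2], length.out = 6)
  plate <- make_calibration_plate(levels, 3,
                                  slope = sc$calibration$slope_AU_per_ug_ml,
                                  intercept = sc$calibration$intercept_AU,
                                  noise = noise)
  write_plate_csv(plate[, c("well", "absorbance")], nm("plate.csv"))
  readr::write_csv(plate[, c("well", "sample_id", "nominal_ug_ml", "role")],
                   nm("layout.csv"))

  truth <- c(sc, list(config = unclass(config), noisy = noisy))
  jsonlite::write_json(truth, nm("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    spectrum = nm("reaction_spectrum.csv"), titration = nm("titration.csv"),
    job = nm("job_series.csv"), edge = nm("tauc_edge.csv"),
    plate = nm("plate.csv"), layout = nm("layout.csv"),
    ground_truth = nm("ground_truth.json")
  ))
}

#' Characterize a charge-transfer complex from files
#'
#' Runs the full physical-chemistry chain — band detection, Benesi-Hildebrand,
#' Tauc band gap, Job stoichiometry, ionization potential and standard free
#' energy — and assembles a characterization report. Oscillator strength,
#' transition dipole and resonance energy are omitted unless their auxiliary
#' inputs (half-bandwidth, electron affinity, Coulomb term) are supplied.
#'
#' @param titration_csv Titration CSV (`donor_conc_M`, `acceptor_conc_M`,
#'   `absorbance`).
#' @param job_csv Job's series CSV (`mole_fraction`, `absorbance`).
#' @param edge_csv Absorption-edge CSV (`energy_eV`, `alpha`).
#' @param spectrum_csv Optional reaction spectrum CSV for band detection.
#' @param config A [run_config()].
#' @param out_json Optional path; when given, the report is written as JSON.
#' @return A `ctc_report` list with fields mirroring the standard
#'   electronic-constants table: `lambda_max_nm`, `ct_energy_eV`,
#'   `K_L_mol`, `epsilon_L_mol_cm`, `ionization_potential_eV`,
#'   `band_gap_eV`, `delta_g0_kJ_mol`, `jobs_x_star`, `molar_ratio`, plus
#'   fit diagnostics and the embedded config.
#' @export
ctc_characterize <- function(titration_csv, job_csv, edge_csv,
                             spectrum_csv = NULL, config = run_config(),
                             out_json = NULL) {
  read_tbl <- function(path, cols) {
    if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
    d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    miss <- setdiff(cols, names(d))
    if (length(miss) > 0) {
      abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
    }
    d
  }
  titration <- read_tbl(titration_csv, c("donor_conc_M", "acceptor_conc_M", "absorbance"))
  job <- read_tbl(job_csv, c("mole_fraction", "absorbance"))
  edge <- read_tbl(edge_csv, c("energy_eV", "alpha"))

  bh <- benesi_hildebrand(titration)
  tauc <- tauc_band_gap(edge, config$tauc_window_min_points, config$tauc_r2_min)
  job_fit <- jobs_ratio(job)

  lambda_max <- NA_real_
  if (!is.null(spectrum_csv)) {
    sp <- read_spectrum_csv(spectrum_csv)
    maxima <- find_band_maxima(sp, config$prominence_frac)
    # the CT band is the longest-wavelength (visible) maximum
    if (nrow(maxima) > 0) lambda_max <- max(maxima$wavelength_nm)
  }

  report <- list(
    lambda_max_nm = lambda_max,
    ct_energy_eV = if (is.na(lambda_max)) NA_real_ else ct_transition_energy(lambda_max),
    ionization_potential_eV = if (is.na(lambda_max)) NA_real_ else ionization_potential(lambda_max),
    K_L_mol = bh$K,
    epsilon_L_mol_cm = bh$epsilon,
    bh_r_squared = bh$r_squared,
    band_gap_eV = tauc$Eg,
    tauc_r_squared = tauc$r_squared,
    delta_g0_kJ_mol = standard_free_energy(bh$K, config$temperature_K),
    jobs_x_star = job_fit$x_star,
    molar_ratio = job_fit$ratio,
    molar_ratio_label = job_fit$ratio_label,
    config = unclass(config)
  )
  class(report) <- "ctc_report"
  if (!is.null(out_json)) {
    jsonlite::write_json(unclass(report), out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.ctc_report <- function(x, ...) {
  cat("Charge-transfer complex characterization\n")
  fmt <- function(lbl, v, u = "") {
    if (!is.na(v)) cat(sprintf("  %-28s %.6g %s\n", lbl, v, u))
  }
  fmt("lambda_max", x$lambda_max_nm, "nm")
  fmt("CT transition energy", x$ct_energy_eV, "eV")
  fmt("Ionization potential", x$ionization_potential_eV, "eV")
  fmt("Association constant K", x$K_L_mol, "L/mol")
  fmt("Molar absorptivity", x$epsilon_L_mol_cm, "L/mol/cm")
  fmt("Band gap Eg", x$band_gap_eV, "eV")
  fmt("Delta G0", x$delta_g0_kJ_mol, "kJ/mol")
  fmt("Job's x*", x$jobs_x_star)
  cat(sprintf("  %-28s %s\n", "Molar ratio",
              if (is.na(x$molar_ratio_label)) sprintf("%.3f", x$molar_ratio)
              else x$molar_ratio_label))
  invisible(x)
}

#' Validate a microwell assay from plate files
#'
#' Fits the calibration from the plate's standard wells (blank-corrected when
#' blanks exist), derives LOD/LOQ, quantifies unknown wells, and summarizes
#' per-sample recovery.
#'
#' @param plate_csv Plate readings CSV (8 x 12 grid, see [read_plate_csv()]).
#' @param layout_csv Layout CSV (see [read_layout_csv()]).
#' @param config A [run_config()].
#' @param out_json Optional JSON output path.
#' @return A list with `calibration` (coefficients, R^2, LOD, LOQ, range),
#'   `unknowns` (per-well quantitation tibble), `sample_summary` (per-sample
#'   recovery/RSD for unknowns with a nominal value), and the embedded config.
#' @export
ctc_validate <- function(plate_csv, layout_csv, config = run_config(),
                         out_json = NULL) {
  readings <- read_plate_csv(plate_csv)
  layout <- read_layout_csv(layout_csv)
  merged <- quantify_unknowns_prep(readings, layout)
  fit <- calibration_from_plate(merged)
  ll <- lod_loq(fit)
  unknowns <- quantify_unknowns(fit, readings, layout) |>
    dplyr::filter(.data$role == "unknown")

  sample_summary <- unknowns |>
    dplyr::filter(!is.na(.data$nominal_ug_ml)) |>
    dplyr::group_by(.data$sample_id, nominal = .data$nominal_ug_ml) |>
    dplyr::summarise(
      n = dplyr::n(),
      found_mean = mean(.data$found_ug_ml),
      label_claim_pct = label_claim(mean(.data$found_ug_ml), unique(nominal)),
      rsd_pct = if (dplyr::n() > 1)
        100 * sd(.data$found_ug_ml) / mean(.data$found_ug_ml) else NA_real_,
      .groups = "drop"
    )

  out <- list(
    calibration = list(
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared, intercept_se = fit$intercept_se,
      lod_ug_ml = ll$lod, loq_ug_ml = ll$loq,
      conc_range_ug_ml = fit$conc_range, n = fit$n
    ),
    unknowns = unknowns,
    sample_summary = sample_summary,
    config = unclass(config)
  )
  if (!is.null(out_json)) {
    ser <- out
    ser$unknowns <- as.data.frame(ser$unknowns)
    ser$sample_summary <- as.data.frame(ser$sample_summary)
    jsonlite::write_json(ser, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}

## join readings to layout so calibration_from_plate sees roles
quantify_unknowns_prep <- function(readings, layout) {
  missing_wells <- setdiff(readings$well, layout$well)
  if (length(missing_wells) > 0) {
    abort(sprintf("no layout entry for read well(s): %s",
                  paste(missing_wells, collapse = ", ")))
  }
  dplyr::inner_join(readings, layout, by = "well")
}

#' Score greenness from a ledger file
#'
#' Reads a penalty ledger (YAML/JSON), computes the Analytical Eco-Scale
#' score, and passes any published GAPI/AGREE outputs through into the
#' report.
#'
#' @param ledger_path Ledger file path.
#' @param out_json Optional JSON output path.
#' @return The `aes_result`, with `gapi`/`agree` passthrough attached.
#' @export
ctc_greenness <- function(ledger_path, out_json = NULL) {
  ledger <- read_ledger(ledger_path)
  res <- aes_score(ledger)
  res$gapi <- attr(ledger, "gapi")
  res$agree <- attr(ledger, "agree")
  if (!is.null(out_json)) {
    ser <- list(
      method = attr(ledger, "method"),
      items = as.data.frame(res$ledger),
      total_pp = res$total_pp, score = res$score,
      classification = res$classification,
      gapi = res$gapi, agree = res$agree
    )
    jsonlite::write_json(ser, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}
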
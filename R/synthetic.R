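#' Noise model for synthetic absorbance data
#'
#' Measurement noise is modelled as additive Gaussian noise (in absorbance
#' units) plus multiplicative Gaussian noise (a fraction of the signal), the
#' usual heteroscedastic picture for plate readers where the error floor is
#' instrumental and the proportional part tracks the signal. Defaults
#' (0.002 AU, 0.5 %) keep synthetic replicate RSDs near the 2 % precision
#' typical of microwell spectrophotometric assays.
#'
#' A seed is mandatory whenever either sd is positive: every generator is a
#' pure function of its parameters and the seed, and no global random state
#' is consumed or left behind.
#'
#' @param sd_absolute Additive noise standard deviation, AU. Non-negative.
#' @param sd_relative Multiplicative noise standard deviation, fraction of
#'   signal. Non-negative.
#' @param seed Integer seed; required if any sd is positive.
#' @return A `noise_model` object.
#' @export
#' @examples
#' noise_model(0, 0)                 # noiseless
#' noise_model(0.002, 0.005, seed = 1)
noise_model <- function(sd_absolute = 0.002, sd_relative = 0.005, seed = NULL) {
  if (sd_absolute < 0 || sd_relative < 0) {
    abort("noise standard deviations must be non-negative")
  }
  if ((sd_absolute > 0 || sd_relative > 0) && is.null(seed)) {
    abort("a seed is required for any stochastic noise model")
  }
  structure(
    list(sd_absolute = sd_absolute, sd_relative = sd_relative, seed = seed),
    class = "noise_model"
  )
}

is_noiseless <- function(noise) {
  noise$sd_absolute == 0 && noise$sd_relative == 0
}

## Evaluate expr with a private RNG stream; the caller's .Random.seed is
## untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

apply_noise <- function(values, noise) {
  if (is_noiseless(noise)) {
    return(values)
  }
  with_seed(noise$seed, {
    n <- length(values)
    values * (1 + rnorm(n, 0, noise$sd_relative)) + rnorm(n, 0, noise$sd_absolute)
  })
}

#' Gaussian band specification
#'
#' One absorption band parameterized in the wavelength domain (center,
#' standard-deviation width, peak height). Wavelength-domain Gaussians are an
#' adequate stand-in for smooth solution-phase bands over the narrow ranges
#' simulated here; no wavenumber-domain asymmetry is modelled.
#'
#' @param center Band center, nm (> 0).
#' @param width Gaussian standard deviation, nm (> 0).
#' @param height Peak absorbance, AU (>= 0).
#' @return A one-row tibble with columns `center`, `width`, `height`. Rows
#'   from several calls can be combined with [dplyr::bind_rows()].
#' @export
#' @examples
#' dplyr::bind_rows(band_spec(530, 30, 0.8), band_spec(310, 12, 0.5))
band_spec <- function(center, width, height) {
  if (center <= 0) abort("band center must be positive (nm)")
  if (width <= 0) abort("band width must be positive (nm)")
  if (height < 0) abort("band height must be non-negative (AU)")
  tibble::tibble(center = center, width = width, height = height)
}

#' Solve the 1:1 complexation equilibrium
#'
#' Closed-form concentration of the complex DA for D + A <-> DA with
#' association constant K, total donor D0 and total acceptor A0:
#' \deqn{[DA] = \frac{(D_0 + A_0 + 1/K) - \sqrt{(D_0 + A_0 + 1/K)^2 - 4 D_0 A_0}}{2}}
#' computed in the numerically stable form 2 D0 A0 / (b + sqrt(b^2 - 4 D0 A0))
#' so that no precision is lost when binding is weak. K = 0 returns 0.
#'
#' All arguments are vectorized and recycled.
#'
#' @param K Association constant, L/mol (>= 0).
#' @param donor_total Total donor concentration D0, mol/L (>= 0).
#' @param acceptor_total Total acceptor concentration A0, mol/L (>= 0).
#' @return Complex concentration, mol/L; always within mass balance
#'   (`0 <= [DA] <= min(D0, A0)`).
#' @export
#' @examples
#' solve_1to1_equilibrium(147, 3.67e-5, 4.79e-3)
#' solve_1to1_equilibrium(0, 1e-3, 1e-3)   # no binding
solve_1to1_equilibrium <- function(K, donor_total, acceptor_total) {
  if (any(K < 0)) abort("association constant K must be non-negative")
  if (any(donor_total < 0) || any(acceptor_total < 0)) {
    abort("total concentrations must be non-negative")
  }
  n <- max(length(K), length(donor_total), length(acceptor_total))
  K <- rep_len(K, n)
  d0 <- rep_len(donor_total, n)
  a0 <- rep_len(acceptor_total, n)
  out <- numeric(n)
  pos <- K > 0 & d0 > 0 & a0 > 0
  b <- d0[pos] + a0[pos] + 1 / K[pos]
  disc <- pmax(b^2 - 4 * d0[pos] * a0[pos], 0)
  out[pos] <- 2 * d0[pos] * a0[pos] / (b + sqrt(disc))
  # guard against last-bit mass-balance violations
  pmin(out, d0, a0)
}

#' Synthesize an absorption spectrum from Gaussian bands
#'
#' Absorbance on the grid is the sum of the Gaussian bands plus noise; the
#' traces are baseline-free, matching the generators' downstream assumption
#' that no baseline-correction stage exists.
#'
#' @param bands Data frame of bands (columns `center`, `width`, `height`, as
#'   built by [band_spec()]); zero rows give a flat zero spectrum.
#' @param wavelengths Strictly ascending wavelength grid, nm.
#' @param noise A [noise_model()].
#' @return A spectrum tibble with columns `wavelength_nm`, `absorbance`.
#' @export
#' @examples
#' sp <- make_spectrum(band_spec(530, 30, 0.8), seq(400, 700, by = 1))
make_spectrum <- function(bands, wavelengths, noise = noise_model(0, 0)) {
  if (length(wavelengths) < 2) abort("wavelength grid needs at least 2 points")
  if (any(diff(wavelengths) <= 0)) abort("wavelength grid must be strictly ascending")
  bands <- tibble::as_tibble(bands)
  absorbance <- rep(0, length(wavelengths))
  if (nrow(bands) > 0) {
    stopifnot(all(c("center", "width", "height") %in% names(bands)))
    for (i in seq_len(nrow(bands))) {
      absorbance <- absorbance +
        bands$height[i] * exp(-((wavelengths - bands$center[i])^2) / (2 * bands$width[i]^2))
    }
  }
  tibble::tibble(
    wavelength_nm = as.numeric(wavelengths),
    absorbance = apply_noise(absorbance, noise)
  )
}

#' Synthesize a donor titration at fixed acceptor concentration
#'
#' Emulates a Benesi-Hildebrand experiment: varying donor concentrations
#' against one fixed acceptor concentration, reading the charge-transfer band.
#'
#' Two generation modes:
#' \describe{
#'   \item{`"equilibrium"`}{absorbance = epsilon * path * \[DA\] with \[DA\]
#'     from [solve_1to1_equilibrium()]; physically exact.}
#'   \item{`"bh_exact"`}{points satisfy the Benesi-Hildebrand line
#'     A0/A = 1/epsilon + 1/(K * epsilon * D0) exactly. Exact-equilibrium data
#'     only approach this line when the acceptor is in large excess, so the two
#'     modes differ by the linearization bias; both are provided so that bias
#'     can be quantified.}
#' }
#'
#' @param donor_concs Donor total concentrations, mol/L; at least 2.
#' @param acceptor_conc Fixed acceptor total concentration, mol/L.
#' @param K Association constant, L/mol.
#' @param epsilon Molar absorptivity of the complex, L/mol/cm.
#' @param path Optical path, cm. The microwell effective path depends on fill
#'   volume, so it is an explicit parameter rather than an assumed constant.
#' @param noise A [noise_model()].
#' @param mode `"equilibrium"` or `"bh_exact"`.
#' @return Tibble with columns `donor_conc_M`, `acceptor_conc_M`, `absorbance`.
#' @export
#' @examples
#' make_titration(seq(3.67e-5, 1.22e-4, length.out = 6), 4.79e-3,
#'                K = 147, epsilon = 1.29e4, mode = "bh_exact")
make_titration <- function(donor_concs, acceptor_conc, K, epsilon, path = 1,
                           noise = noise_model(0, 0),
                           mode = c("equilibrium", "bh_exact")) {
  mode <- match.arg(mode)
  if (length(donor_concs) < 2) abort("at least 2 donor concentrations are required")
  if (any(donor_concs <= 0) || acceptor_conc <= 0) {
    abort("concentrations must be positive")
  }
  if (K <= 0 || epsilon <= 0 || path <= 0) abort("K, epsilon and path must be positive")
  absorbance <- switch(mode,
    equilibrium = epsilon * path *
      solve_1to1_equilibrium(K, donor_concs, acceptor_conc),
    bh_exact = acceptor_conc / (1 / epsilon + 1 / (K * epsilon * donor_concs))
  )
  tibble::tibble(
    donor_conc_M = as.numeric(donor_concs),
    acceptor_conc_M = acceptor_conc,
    absorbance = apply_noise(absorbance, noise)
  )
}

#' Synthesize a Job's continuous-variation series
#'
#' At each mole fraction x of donor, the totals are D0 = x * C and
#' A0 = (1 - x) * C at fixed total molarity C; the absorbance follows from the
#' exact 1:1 equilibrium. For a 1:1 complex the noiseless curve is symmetric
#' about x = 0.5 and maximal there.
#'
#' @param total_conc Total molarity C, mol/L.
#' @param K Association constant, L/mol.
#' @param epsilon Molar absorptivity, L/mol/cm.
#' @param fractions Donor mole fractions in \[0, 1\].
#' @param path Optical path, cm.
#' @param noise A [noise_model()].
#' @return Tibble with columns `mole_fraction`, `total_conc_M`, `absorbance`.
#' @export
#' @examples
#' make_job_series(2e-3, K = 150, epsilon = 1.29e4,
#'                 fractions = seq(0.1, 0.9, by = 0.1))
make_job_series <- function(total_conc, K, epsilon, fractions, path = 1,
                            noise = noise_model(0, 0)) {
  if (any(fractions < 0 | fractions > 1)) {
    abort("mole fractions must lie in [0, 1]")
  }
  if (total_conc <= 0 || K <= 0 || epsilon <= 0 || path <= 0) {
    abort("total_conc, K, epsilon and path must be positive")
  }
  ca <- solve_1to1_equilibrium(K, fractions * total_conc, (1 - fractions) * total_conc)
  tibble::tibble(
    mole_fraction = as.numeric(fractions),
    total_conc_M = total_conc,
    absorbance = apply_noise(epsilon * path * ca, noise)
  )
}

#' Synthesize a direct-transition absorption edge
#'
#' For a direct allowed transition the absorption coefficient obeys
#' (alpha * h nu)^2 = B * (h nu - Eg) above the gap, i.e.
#' alpha = sqrt(B * (h nu - Eg)) / (h nu), and is zero below it. Noise is
#' applied to alpha, which is where an instrument would add it.
#'
#' @param Eg Band-gap energy, eV (> 0).
#' @param B Edge coefficient (> 0); sets the edge steepness.
#' @param energies Photon-energy grid, eV, strictly ascending.
#' @param noise A [noise_model()].
#' @return Tibble with columns `energy_eV`, `alpha`.
#' @export
#' @examples
#' make_tauc_edge(1.9, B = 1, energies = seq(1.5, 3.5, by = 0.01))
make_tauc_edge <- function(Eg, B = 1, energies, noise = noise_model(0, 0)) {
  if (Eg <= 0) abort("band gap Eg must be positive (eV)")
  if (B <= 0) abort("edge coefficient B must be positive")
  if (length(energies) < 2 || any(diff(energies) <= 0)) {
    abort("photon-energy grid must be strictly ascending with >= 2 points")
  }
  alpha <- ifelse(energies > Eg, sqrt(B * pmax(energies - Eg, 0)) / energies, 0)
  tibble::tibble(
    energy_eV = as.numeric(energies),
    alpha = apply_noise(alpha, noise)
  )
}

#' Synthesize a 96-well calibration plate
#'
#' Well absorbances follow the straight line intercept + slope * C with plate
#' noise, laid out row-major (A1..A12, then B1..) with each concentration
#' level occupying `replicates` consecutive wells.
#'
#' @param conc_levels Nominal concentrations, one per level (ug/mL).
#' @param replicates Wells per level.
#' @param slope Calibration slope, AU per ug/mL.
#' @param intercept Calibration intercept, AU.
#' @param noise A [noise_model()].
#' @param role Role recorded for every well (default `"standard"`).
#' @return Tibble with columns `well`, `plate_row`, `plate_col`, `sample_id`,
#'   `nominal_ug_ml`, `role`, `absorbance`.
#' @export
#' @examples
#' make_calibration_plate(c(5, 20, 40, 80, 120), 3,
#'                        slope = 0.0289, intercept = 0.0887)
make_calibration_plate <- function(conc_levels, replicates, slope, intercept,
                                   noise = noise_model(0, 0),
                                   role = "standard") {
  n_wells <- length(conc_levels) * replicates
  if (n_wells > 96) {
    abort(sprintf("requested %d wells but a plate has only 96", n_wells))
  }
  if (replicates < 1) abort("replicates must be at least 1")
  conc <- rep(conc_levels, each = replicates)
  idx <- seq_len(n_wells)
  rows <- LETTERS[((idx - 1) %/% 12) + 1]
  cols <- ((idx - 1) %% 12) + 1
  tibble::tibble(
    well = paste0(rows, cols),
    plate_row = rows,
    plate_col = cols,
    sample_id = paste0("std_", rep(seq_along(conc_levels), each = replicates),
                       "_r", rep(seq_len(replicates), length(conc_levels))),
    nominal_ug_ml = conc,
    role = role,
    absorbance = apply_noise(intercept + slope * conc, noise)
  )
}
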
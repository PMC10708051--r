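#' Benesi-Hildebrand association-constant fit
#'
#' Linearizes 1:1 binding at fixed acceptor concentration by ordinary least
#' squares of y = \[A0\]/A on x = 1/\[D0\]:
#' \deqn{\frac{[A_0]}{A} = \frac{1}{\varepsilon} + \frac{1}{K\,\varepsilon\,[D_0]}}
#' so epsilon = 1/intercept and K = intercept/slope. The regression is
#' unweighted, as is standard practice for these plots; K comes from the line,
#' not from a nonlinear refit. The linearization is exact only when the fixed
#' species is in large excess; on exact-equilibrium data at moderate excess the
#' fitted K carries a small bias that [make_titration()]'s two modes let you
#' quantify.
#'
#' @param titration Data frame with columns `donor_conc_M`, `acceptor_conc_M`
#'   (constant), `absorbance`; at least 5 points, absorbances positive.
#' @return A `bh_fit` object with elements `K` (L/mol), `epsilon` (L/mol/cm),
#'   `r_squared`, `slope`, `intercept`, `n`, and the transformed `data`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' t <- make_titration(seq(3.67e-5, 1.22e-4, length.out = 6), 4.79e-3,
#'                     K = 147, epsilon = 1.29e4, mode = "bh_exact")
#' benesi_hildebrand(t)
benesi_hildebrand <- function(titration) {
  titration <- tibble::as_tibble(titration)
  need <- c("donor_conc_M", "acceptor_conc_M", "absorbance")
  if (!all(need %in% names(titration))) {
    abort(sprintf("titration needs columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(titration) < 5) abort("Benesi-Hildebrand fit needs at least 5 points")
  if (any(titration$absorbance <= 0)) abort("absorbances must be positive for B-H analysis")
  if (any(titration$donor_conc_M <= 0)) abort("donor concentrations must be positive")
  a0 <- unique(titration$acceptor_conc_M)
  if (length(a0) != 1) abort("acceptor concentration must be fixed across the series")

  bh <- tibble::tibble(
    x = 1 / titration$donor_conc_M,
    y = a0 / titration$absorbance
  )
  fit <- lm(y ~ x, data = bh)
  intercept <- coef(fit)[[1]]
  slope <- coef(fit)[[2]]
  if (intercept <= 0 || slope <= 0) {
    abort("B-H model inapplicable: non-positive slope or intercept")
  }
  structure(
    list(
      K = intercept / slope,
      epsilon = 1 / intercept,
      r_squared = summary(fit)$r.squared,
      slope = slope,
      intercept = intercept,
      n = nrow(bh),
      data = bh,
      lm = fit
    ),
    class = "bh_fit"
  )
}

#' @export
print.bh_fit <- function(x, ...) {
  cat("Benesi-Hildebrand fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  K       = %.4g L/mol\n", x$K))
  cat(sprintf("  epsilon = %.4g L/mol/cm\n", x$epsilon))
  cat(sprintf("  R^2     = %.6f\n", x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bh_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"]
  )
}

#' @exportS3Method generics::glance
glance.bh_fit <- function(x, ...) {
  tibble::tibble(K = x$K, epsilon = x$epsilon, r.squared = x$r_squared, nobs = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bh_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = expression(1 / "[D]" ~ (L / mol)),
                  y = expression("[A]" / A),
                  title = sprintf("Benesi-Hildebrand: K = %.3g L/mol", object$K))
}

#' Tauc-plot band-gap extraction
#'
#' For a direct allowed transition, (alpha h nu)^2 is linear in photon energy
#' above the gap; the band gap Eg is the x-intercept of that linear region.
#' The linear region is found automatically: all contiguous windows of at
#' least `window_min_points` points are scanned; among windows whose linear
#' fit reaches `r2_min`, the longest wins, with ties going to the steeper
#' window. Length, not slope, is the primary criterion because the
#' x-intercept is an extrapolation whose error shrinks with window span,
#' whereas picking the steepest of many candidate windows under noise
#' systematically selects upward-fluctuating short fits and biases the gap
#' upward.
#'
#' @param edge Data frame with columns `energy_eV`, `alpha` (absorption
#'   coefficient), as from [make_tauc_edge()] or read from file.
#' @param window_min_points Minimum window length (default 5).
#' @param r2_min Minimum R-squared for a window to count as linear
#'   (default 0.99).
#' @param min_signal_frac Points whose (alpha h nu)^2 falls below this
#'   fraction of its maximum are excluded from the window scan (default
#'   0.05). At the foot of the edge the signal — and with it any
#'   signal-proportional noise — is so small that short windows there look
#'   spuriously linear and steep; the transition itself carries the gap
#'   information, and extrapolating from it is unaffected because every
#'   sub-window of an exactly linear region has the same x-intercept.
#' @return A `tauc_fit` with elements `Eg` (eV), `slope`, `intercept`,
#'   `r_squared`, `window` (row indices used), `n`, `data` (with the
#'   transformed `tauc_y` column). Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' edge <- make_tauc_edge(1.9, B = 1, energies = seq(1.5, 3.5, by = 0.01))
#' tauc_band_gap(edge)$Eg
tauc_band_gap <- function(edge, window_min_points = 5, r2_min = 0.99,
                          min_signal_frac = 0.05) {
  edge <- tibble::as_tibble(edge)
  if (!all(c("energy_eV", "alpha") %in% names(edge))) {
    abort("edge needs columns `energy_eV` and `alpha`")
  }
  if (window_min_points < 3) abort("window_min_points must be at least 3")
  edge <- dplyr::arrange(edge, .data$energy_eV)
  x_all <- edge$energy_eV
  y_all <- (edge$alpha * x_all)^2
  scan <- y_all >= min_signal_frac * max(y_all)
  x <- x_all[scan]
  y <- y_all[scan]
  n <- length(x)
  if (n < window_min_points) abort("not enough points for the requested window")

  # cumulative sums make each window's OLS O(1); the scan is O(n^2) windows
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  wsum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0

  best <- NULL
  for (i in seq_len(n - window_min_points + 1)) {
    for (j in seq(i + window_min_points - 1, n)) {
      m <- j - i + 1
      sx <- wsum(cx, i, j); sy <- wsum(cy, i, j)
      sxx <- wsum(cxx, i, j); syy <- wsum(cyy, i, j); sxy <- wsum(cxy, i, j)
      ssxx <- sxx - sx^2 / m
      ssyy <- syy - sy^2 / m
      ssxy <- sxy - sx * sy / m
      if (ssxx <= 0 || ssyy <= .Machine$double.eps) next
      slope <- ssxy / ssxx
      r2 <- ssxy^2 / (ssxx * ssyy)
      if (slope <= 0 || r2 < r2_min) next
      better <- is.null(best) || m > best$m ||
        (m == best$m && slope > best$slope)
      if (better) {
        best <- list(i = i, j = j, m = m, slope = slope,
                     intercept = (sy - slope * sx) / m, r2 = r2)
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "no linear region: no window of >= %d points reached R^2 >= %g",
      window_min_points, r2_min
    ))
  }
  structure(
    list(
      Eg = -best$intercept / best$slope,
      slope = best$slope,
      intercept = best$intercept,
      r_squared = best$r2,
      window = which(scan)[c(best$i, best$j)],
      n = length(x_all),
      data = tibble::tibble(energy_eV = x_all, alpha = edge$alpha, tauc_y = y_all)
    ),
    class = "tauc_fit"
  )
}

#' @export
print.tauc_fit <- function(x, ...) {
  cat(sprintf("Tauc fit: Eg = %.4f eV (window rows %d-%d of %d, R^2 = %.5f)\n",
              x$Eg, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tauc_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.tauc_fit <- function(x, ...) {
  tibble::tibble(Eg = x$Eg, r.squared = x$r_squared,
                 window_points = x$window[2] - x$window[1] + 1, nobs = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.tauc_fit <- function(object, ...) {
  d <- object$data
  win <- d[object$window[1]:object$window[2], ]
  ggplot2::ggplot(d, ggplot2::aes(.data$energy_eV, .data$tauc_y)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_point(data = win, colour = "steelblue", size = 0.9) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$Eg, linetype = "dashed") +
    ggplot2::labs(x = expression(h * nu ~ (eV)),
                  y = expression((alpha * h * nu)^2),
                  title = sprintf("Tauc plot: Eg = %.3f eV", object$Eg))
}

#' Photon energy of a band maximum
#'
#' E (eV) = 1239.84 / lambda (nm).
#'
#' @param lambda_max Wavelength, nm (> 0). Vectorized.
#' @return Photon energy, eV.
#' @export
#' @examples
#' ct_transition_energy(530)  # 2.339 eV
ct_transition_energy <- function(lambda_max) {
  if (any(lambda_max <= 0)) abort("wavelength must be positive")
  EV_NM / lambda_max
}

#' Donor ionization potential from the CT band position
#'
#' Empirical relation for charge-transfer complexes:
#' Ip (eV) = 5.76 + 1.53e-4 * nu, with nu the band-maximum wavenumber in
#' cm^-1 (nu = 1e7 / lambda(nm)).
#'
#' @param lambda_max CT band maximum, nm (> 0). Vectorized.
#' @return Ionization potential, eV.
#' @export
#' @examples
#' ionization_potential(530)  # 8.65
#' ionization_potential(470)  # 9.02
ionization_potential <- function(lambda_max) {
  if (any(lambda_max <= 0)) abort("wavelength must be positive")
  5.76 + 1.53e-4 * (1e7 / lambda_max)
}

#' Standard free energy of complex formation
#'
#' Delta G0 = -R T ln K, returned in kJ/mol (R = 8.314 J/(mol K)). Negative
#' exactly when K > 1. The default temperature is 298 K.
#'
#' @param K Association constant, L/mol (> 0). Vectorized.
#' @param temperature Kelvin (default 298).
#' @return Standard free energy change, kJ/mol.
#' @export
#' @examples
#' standard_free_energy(147)  # -12.36 kJ/mol
standard_free_energy <- function(K, temperature = 298) {
  if (any(K <= 0)) abort("K must be positive")
  if (temperature <= 0) abort("temperature must be positive (K)")
  -GAS_CONSTANT * temperature * log(K) / 1000
}

#' Oscillator strength of a CT band
#'
#' f = 4.32e-9 * epsilon_max * delta_nu_half. The half-bandwidth must be
#' supplied by the caller — it comes from the measured band shape and no
#' default is guessed.
#'
#' @param epsilon_max Molar absorptivity at the maximum, L/mol/cm.
#' @param half_bandwidth Band full width at half maximum, cm^-1.
#' @return Oscillator strength (unitless).
#' @export
#' @examples
#' oscillator_strength(1e4, 1e4)  # 0.432
oscillator_strength <- function(epsilon_max, half_bandwidth) {
  if (missing(epsilon_max) || missing(half_bandwidth) ||
      is.null(epsilon_max) || is.null(half_bandwidth)) {
    abort("insufficient data: epsilon_max and half_bandwidth are both required")
  }
  if (any(epsilon_max < 0) || any(half_bandwidth < 0)) abort("inputs must be non-negative")
  4.32e-9 * epsilon_max * half_bandwidth
}

#' Transition dipole moment of a CT band
#'
#' mu (Debye) = 0.0958 * sqrt(epsilon_max * delta_nu_half / nu_max).
#'
#' @param epsilon_max Molar absorptivity at the maximum, L/mol/cm.
#' @param half_bandwidth Band full width at half maximum, cm^-1.
#' @param nu_max Band-maximum wavenumber, cm^-1.
#' @return Transition dipole moment, Debye.
#' @export
transition_dipole <- function(epsilon_max, half_bandwidth, nu_max) {
  if (missing(epsilon_max) || missing(half_bandwidth) || missing(nu_max)) {
    abort("insufficient data: epsilon_max, half_bandwidth and nu_max are all required")
  }
  if (any(epsilon_max < 0) || any(half_bandwidth < 0) || any(nu_max <= 0)) {
    abort("epsilon_max and half_bandwidth must be non-negative; nu_max positive")
  }
  0.0958 * sqrt(epsilon_max * half_bandwidth / nu_max)
}

#' Resonance energy of the CT transition
#'
#' From the transition-energy balance h nu_CT = Ip - EA - W + R_N, so
#' R_N = h nu_CT - Ip + EA + W. The acceptor electron affinity EA and the
#' Coulomb term W are physical inputs the caller must supply; there is no
#' defensible default.
#'
#' @param ip Donor ionization potential, eV.
#' @param electron_affinity Acceptor electron affinity EA, eV.
#' @param coulomb_term Coulombic interaction term W, eV.
#' @param ct_energy CT transition energy h nu_CT, eV.
#' @return Resonance energy, eV.
#' @export
resonance_energy <- function(ip, electron_affinity, coulomb_term, ct_energy) {
  if (missing(ip) || missing(electron_affinity) || missing(coulomb_term) ||
      missing(ct_energy)) {
    abort("insufficient data: ip, electron_affinity, coulomb_term and ct_energy are all required")
  }
  ct_energy - ip + electron_affinity + coulomb_term
}

#' Job's continuous-variation stoichiometry
#'
#' Locates the mole fraction x* at maximum absorbance by fitting a parabola to
#' the 5 points centered on the empirical maximum (clamped to the grid edge
#' when the maximum is the 2nd or 2nd-to-last point) and taking the vertex.
#' The donor:acceptor ratio is x*/(1 - x*), also matched to the nearest small
#' integer ratio among 1:2, 1:1, 2:1 when x* is within 0.1 (mole-fraction
#' units) of 1/3, 1/2 or 2/3. The estimate is invariant to uniform scaling of
#' the absorbances. A maximum on the first or last grid point is an error: the
#' series does not bracket the stoichiometric point.
#'
#' @param job Data frame with columns `mole_fraction` (ascending, in \[0,1\])
#'   and `absorbance`; at least 5 points.
#' @return A `job_fit` with `x_star`, `ratio` (numeric), `ratio_label`
#'   ("1:2", "1:1", "2:1" or NA), `data`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' j <- make_job_series(2e-3, 150, 1.29e4, seq(0.1, 0.9, by = 0.1))
#' jobs_ratio(j)
jobs_ratio <- function(job) {
  job <- tibble::as_tibble(job)
  if (!all(c("mole_fraction", "absorbance") %in% names(job))) {
    abort("job series needs columns `mole_fraction` and `absorbance`")
  }
  if (nrow(job) < 5) abort("Job's analysis needs at least 5 points")
  if (is.unsorted(job$mole_fraction, strictly = TRUE)) {
    abort("mole fractions must be strictly ascending")
  }
  x <- job$mole_fraction
  a <- job$absorbance
  n <- length(x)
  imax <- which.max(a)  # which.max already ties toward lower x
  if (imax == 1 || imax == n) {
    abort("no interior maximum: absorbance peaks at a boundary mole fraction")
  }
  lo <- max(1, min(imax - 2, n - 4))
  hi <- lo + 4
  x_star <- parabola_vertex3(x[lo:hi], a[lo:hi])
  ratio <- x_star / (1 - x_star)
  candidates <- c("1:2" = 1 / 3, "1:1" = 1 / 2, "2:1" = 2 / 3)
  d <- abs(candidates - x_star)
  label <- if (min(d) <= 0.1) names(candidates)[which.min(d)] else NA_character_
  structure(
    list(x_star = x_star, ratio = ratio, ratio_label = label,
         window = c(lo, hi), data = job),
    class = "job_fit"
  )
}

## Vertex of the least-squares parabola through >= 3 points; falls back to
## the empirical maximum when the quadratic term is not concave.
parabola_vertex3 <- function(x, y) {
  fit <- lm(y ~ x + I(x^2))
  c2 <- coef(fit)[[3]]
  if (!is.finite(c2) || c2 >= 0) {
    return(x[which.max(y)])
  }
  -coef(fit)[[2]] / (2 * c2)
}

#' @export
print.job_fit <- function(x, ...) {
  cat(sprintf("Job's method: x* = %.4f, donor:acceptor ratio = %.3f (%s)\n",
              x$x_star, x$ratio,
              if (is.na(x$ratio_label)) "no small-integer match" else x$ratio_label))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.job_fit <- function(x, ...) {
  tibble::tibble(term = c("x_star", "ratio"), estimate = c(x$x_star, x$ratio))
}

#' @exportS3Method generics::glance
glance.job_fit <- function(x, ...) {
  tibble::tibble(x_star = x$x_star, ratio = x$ratio,
                 ratio_label = x$ratio_label, nobs = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.job_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mole_fraction, .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted", colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$x_star, colour = "steelblue") +
    ggplot2::labs(x = "Donor mole fraction", y = "Absorbance (AU)",
                  title = sprintf("Job's plot: x* = %.3f", object$x_star))
}

#' Rank candidate electron-donor sites by summed partial charge
#'
#' Scores each named site (a group of atom numbers) by the absolute value of
#' the signed sum of its atoms' partial charges, then sorts descending. The
#' most negative accumulated charge marks the moiety most able to donate
#' electron density to a pi-acceptor.
#'
#' @param charges Data frame with columns `atom_number` (unique positive
#'   integers), `atom_type`, `partial_charge` (elementary charges e). The
#'   packaged table for the bundled donor is at
#'   `system.file("extdata", "rux_partial_charges.csv", package = "ctcassay")`.
#' @param sites Named list of integer vectors of atom numbers.
#' @return Tibble with columns `site`, `atoms`, `score`, `signed_sum`, sorted
#'   by descending score. The score of an empty site is 0.
#' @export
#' @examples
#' charges <- read_charge_table(
#'   system.file("extdata", "rux_partial_charges.csv", package = "ctcassay")
#' )
#' donor_site_ranking(charges, list(
#'   pyrimidinyl_pyrazole_N6_N7 = c(6, 7),
#'   pyrrole_N12 = 12
#' ))
donor_site_ranking <- function(charges, sites) {
  charges <- tibble::as_tibble(charges)
  need <- c("atom_number", "partial_charge")
  if (!all(need %in% names(charges))) {
    abort("charge table needs columns `atom_number` and `partial_charge`")
  }
  if (anyDuplicated(charges$atom_number)) abort("atom numbers must be unique")
  if (any(charges$atom_number <= 0)) abort("atom numbers must be positive")
  if (is.null(names(sites)) || any(names(sites) == "")) {
    abort("sites must be a named list of atom-number vectors")
  }
  lookup <- setNames(charges$partial_charge, charges$atom_number)
  rows <- purrr::imap(sites, function(atoms, name) {
    missing_atoms <- setdiff(atoms, charges$atom_number)
    if (length(missing_atoms) > 0) {
      abort(sprintf("site '%s' refers to atom(s) absent from the charge table: %s",
                    name, paste(missing_atoms, collapse = ", ")))
    }
    s <- sum(lookup[as.character(atoms)])
    if (length(atoms) == 0) s <- 0
    tibble::tibble(
      site = name,
      atoms = paste(atoms, collapse = ","),
      signed_sum = s,
      score = abs(s)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$score))
}

#' Read a partial-charge atom table
#'
#' CSV with columns `atom_number`, `atom_type`, `partial_charge`.
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("charge table not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    atom_number = readr::col_integer(),
    atom_type = readr::col_character(),
    partial_charge = readr::col_double()
  ), show_col_types = FALSE)
}

#' Concentration unit conversions
#'
#' Convert mass concentration (ug/mL) to molarity (mol/L) and back, given the
#' analyte molar mass. The default 306.37 g/mol is the free-base molar mass of
#' the bundled donor drug (C17H18N6).
#'
#' @param x Concentration to convert (vectorized).
#' @param molar_mass Analyte molar mass, g/mol.
#' @return Converted concentration.
#' @export
#' @examples
#' ugml_to_molar(11.25)  # 3.67e-5 M
ugml_to_molar <- function(x, molar_mass = 306.37) {
  if (molar_mass <= 0) abort("molar mass must be positive")
  x * 1e-3 / molar_mass
}

#' @rdname ugml_to_molar
#' @export
molar_to_ugml <- function(x, molar_mass = 306.37) {
  if (molar_mass <= 0) abort("molar mass must be positive")
  x * molar_mass * 1e3
}
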
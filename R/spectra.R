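#' Validate a spectrum data frame
#'
#' A spectrum is a data frame with numeric columns `wavelength_nm` (strictly
#' ascending) and `absorbance`, all values finite, at least 2 rows. Returns
#' the (possibly re-sorted) tibble invisibly coerced; used by every consumer.
#'
#' @param spectrum Data frame with columns `wavelength_nm`, `absorbance`.
#' @param sort If `TRUE`, unsorted rows are sorted ascending with a warning
#'   instead of erroring.
#' @return The validated spectrum tibble.
#' @export
validate_spectrum <- function(spectrum, sort = FALSE) {
  spectrum <- tibble::as_tibble(spectrum)
  if (!all(c("wavelength_nm", "absorbance") %in% names(spectrum))) {
    abort("spectrum needs columns `wavelength_nm` and `absorbance`")
  }
  if (nrow(spectrum) < 2) abort("spectrum needs at least 2 points")
  w <- spectrum$wavelength_nm
  a <- spectrum$absorbance
  if (!is.numeric(w) || !is.numeric(a)) abort("spectrum columns must be numeric")
  if (!all(is.finite(w)) || !all(is.finite(a))) abort("spectrum values must be finite")
  if (anyDuplicated(w)) {
    dup <- w[duplicated(w)][1]
    abort(sprintf("duplicate wavelength %g nm in spectrum", dup))
  }
  if (is.unsorted(w)) {
    if (!sort) abort("wavelengths must be strictly ascending")
    warn("spectrum wavelengths were not ascending; rows sorted")
    spectrum <- dplyr::arrange(spectrum, .data$wavelength_nm)
  }
  spectrum
}

#' Read a two-column spectrum CSV
#'
#' Dialect: header `wavelength_nm,absorbance`, `#`-prefixed comment lines
#' permitted. Rows in descending order are sorted (with a warning); duplicate
#' wavelengths or non-numeric rows are format errors naming the offender.
#'
#' @param path Path to the CSV file.
#' @return A spectrum tibble (`wavelength_nm`, `absorbance`).
#' @export
#' @seealso [write_spectrum_csv()]
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("spectrum file not found: %s", path))
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE)
  if (ncol(raw) < 2) abort(sprintf("%s: expected 2 columns, found %d", path, ncol(raw)))
  raw <- raw[, 1:2]
  names(raw) <- c("wavelength_nm", "absorbance")
  w <- suppressWarnings(as.numeric(raw$wavelength_nm))
  a <- suppressWarnings(as.numeric(raw$absorbance))
  bad <- which(is.na(w) | is.na(a))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric value on data row %d", path, bad[1]))
  }
  validate_spectrum(tibble::tibble(wavelength_nm = w, absorbance = a), sort = TRUE)
}

#' Write a spectrum to CSV
#'
#' @param spectrum A spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  spectrum <- validate_spectrum(spectrum)
  readr::write_csv(spectrum[, c("wavelength_nm", "absorbance")], path)
  invisible(path)
}

## Parabola vertex through three (x, y) points; returns the x of the vertex,
## or the middle x when the points are collinear.
parabola_vertex <- function(x, y) {
  fit <- lm(y ~ x + I(x^2))
  c2 <- coef(fit)[[3]]
  if (!is.finite(c2) || c2 >= 0 || abs(c2) < .Machine$double.eps) {
    return(x[2])
  }
  -coef(fit)[[2]] / (2 * c2)
}

#' Detect absorption band maxima
#'
#' Finds local maxima whose topographic prominence is at least
#' `prominence_frac` times the global maximum absorbance, then refines each
#' peak position by a parabola through the peak point and its two neighbours.
#' Plateau peaks resolve to their shortest-wavelength point. Detection is
#' invariant to uniform scaling of the absorbance axis.
#'
#' @param spectrum A spectrum tibble.
#' @param prominence_frac Minimum prominence as a fraction of the global
#'   maximum (default 0.05, which resolves typical well-separated UV bands
#'   without picking up noise ripple).
#' @return Tibble with columns `wavelength_nm` (refined), `absorbance`
#'   (at the grid peak), sorted by wavelength. Zero rows for a flat spectrum.
#' @export
#' @examples
#' sp <- make_spectrum(dplyr::bind_rows(
#'   band_spec(225, 8, 0.9), band_spec(253, 10, 0.7), band_spec(310, 12, 0.8)
#' ), seq(200, 400, by = 0.5))
#' find_band_maxima(sp)
find_band_maxima <- function(spectrum, prominence_frac = 0.05) {
  spectrum <- validate_spectrum(spectrum)
  w <- spectrum$wavelength_nm
  a <- spectrum$absorbance
  n <- length(a)
  gmax <- max(a)
  if (diff(range(a)) == 0) {
    return(tibble::tibble(wavelength_nm = numeric(), absorbance = numeric()))
  }
  # candidate local maxima: >= both neighbours, > at least one (ties resolve
  # toward shorter wavelength via the strict-left condition)
  cand <- which(
    seq_len(n) > 1 & seq_len(n) < n &
      a >= c(Inf, a[-n]) & a >= c(a[-1], Inf) &
      (a > c(Inf, a[-n]) | a > c(a[-1], Inf))
  )
  # a flat-topped peak yields candidates at both plateau ends; keep the
  # shorter-wavelength one
  cand <- cand[a[cand - 1] != a[cand]]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right to the nearest strictly higher point; prominence is the
    # drop to the higher of the two intervening minima
    left <- a[seq_len(i - 1)]
    higher_l <- which(left > a[i])
    lmin <- if (length(higher_l) > 0) min(a[(max(higher_l) + 1):(i - 1)]) else min(left)
    right <- a[(i + 1):n]
    higher_r <- which(right > a[i])
    rmin <- if (length(higher_r) > 0) min(right[seq_len(min(higher_r) - 1)]) else min(right)
    prominence <- a[i] - max(lmin, rmin)
    keep[k] <- prominence >= prominence_frac * gmax
  }
  cand <- cand[keep]
  if (length(cand) == 0) {
    return(tibble::tibble(wavelength_nm = numeric(), absorbance = numeric()))
  }
  refined <- vapply(cand, function(i) {
    parabola_vertex(w[(i - 1):(i + 1)], a[(i - 1):(i + 1)])
  }, numeric(1))
  out <- tibble::tibble(wavelength_nm = refined, absorbance = a[cand])
  dplyr::arrange(out, .data$wavelength_nm)
}

#' Report new bands formed in a reaction mixture
#'
#' Lists band maxima present in the reaction spectrum but absent (no maximum
#' within `min_shift_nm`) from both reactant spectra — the standard evidence
#' for charge-transfer complex formation, where a new visible band appears
#' that neither the donor nor the acceptor shows alone.
#'
#' @param reaction Spectrum of the reaction mixture.
#' @param donor Spectrum of the donor alone.
#' @param acceptor Spectrum of the acceptor alone.
#' @param min_shift_nm A reaction maximum closer than this to any reactant
#'   maximum is considered the same band (default 10 nm).
#' @param prominence_frac Passed to [find_band_maxima()].
#' @return Tibble of new-band maxima (`wavelength_nm`, `absorbance`).
#' @export
ct_band_shift_check <- function(reaction, donor, acceptor, min_shift_nm = 10,
                                prominence_frac = 0.05) {
  reaction <- validate_spectrum(reaction)
  donor <- validate_spectrum(donor)
  acceptor <- validate_spectrum(acceptor)
  rng <- function(s) range(s$wavelength_nm)
  overlap <- function(r1, r2) r1[1] <= r2[2] && r2[1] <= r1[2]
  if (!overlap(rng(reaction), rng(donor)) || !overlap(rng(reaction), rng(acceptor))) {
    abort("spectra wavelength ranges do not overlap")
  }
  rx <- find_band_maxima(reaction, prominence_frac)
  known <- c(
    find_band_maxima(donor, prominence_frac)$wavelength_nm,
    find_band_maxima(acceptor, prominence_frac)$wavelength_nm
  )
  if (nrow(rx) == 0) return(rx)
  is_new <- vapply(rx$wavelength_nm, function(wl) {
    length(known) == 0 || all(abs(known - wl) > min_shift_nm)
  }, logical(1))
  rx[is_new, ]
}

#' Plot a spectrum
#'
#' @param spectrum A spectrum tibble.
#' @param maxima Optional output of [find_band_maxima()] to annotate.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, maxima = NULL) {
  spectrum <- validate_spectrum(spectrum)
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(.data$wavelength_nm, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)")
  if (!is.null(maxima) && nrow(maxima) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = maxima$wavelength_nm, linetype = "dashed", colour = "grey50"
    )
  }
  p
}
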
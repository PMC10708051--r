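bh_fit_quiet <- function(t) suppressWarnings(benesi_hildebrand(t))

test_that("Benesi-Hildebrand recovers exact-line parameters", {
  d <- seq(3.67e-5, 1.22e-4, length.out = 6)
  t <- make_titration(d, 4.79e-3, K = 147, epsilon = 1.29e4, mode = "bh_exact")
  fit <- bh_fit_quiet(t)
  expect_equal(fit$K, 147, tolerance = 1e-6)
  expect_equal(fit$epsilon, 1.29e4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # exactness holds for arbitrary positive (K, epsilon)
  for (p in list(c(12, 800), c(2500, 5e4))) {
    t2 <- make_titration(d, 1e-3, K = p[1], epsilon = p[2], mode = "bh_exact")
    f2 <- bh_fit_quiet(t2)
    expect_equal(f2$K, p[1], tolerance = 1e-8)
    expect_equal(f2$epsilon, p[2], tolerance = 1e-8)
  }
})

test_that("points on the unit line give K = 1, epsilon = 1", {
  # y = 1 + 1*x with y = [A0]/A, x = 1/[D0]
  d <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  a0 <- 2
  t <- tibble::tibble(
    donor_conc_M = d,
    acceptor_conc_M = a0,
    absorbance = a0 / (1 + 1 / d)
  )
  fit <- bh_fit_quiet(t)
  expect_equal(fit$K, 1, tolerance = 1e-9)
  expect_equal(fit$epsilon, 1, tolerance = 1e-9)
})

test_that("linearization bias on exact-equilibrium data is small at 100x excess", {
  # the linearization assumes the varied species stays effectively free, so
  # the donor must be in large excess over the fixed acceptor
  d <- seq(1e-4, 1e-3, length.out = 8)
  t <- make_titration(d, 1e-6, K = 500, epsilon = 1e4, mode = "equilibrium")
  fit <- bh_fit_quiet(t)
  expect_equal(fit$K, 500, tolerance = 0.02)
})

test_that("B-H on equilibrium data with the acceptor in excess is biased low", {
  # the mirrored configuration (fixed species in 100x excess) breaks the
  # linearization assumption: the fitted K collapses, which is why the
  # bh_exact generator mode exists for line-recovery checks
  d <- seq(1e-5, 1e-4, length.out = 8)
  t <- make_titration(d, 1e-2, K = 500, epsilon = 1e4, mode = "equilibrium")
  fit <- bh_fit_quiet(t)
  expect_lt(fit$K, 100)
})

test_that("inapplicable B-H data raise an explicit error", {
  t <- tibble::tibble(
    donor_conc_M = seq(1e-4, 5e-4, length.out = 5),
    acceptor_conc_M = 1e-3,
    absorbance = c(0.5, 0.4, 0.3, 0.2, 0.1)  # decreasing: negative slope in BH space
  )
  expect_error(bh_fit_quiet(t), "inapplicable")
  expect_error(bh_fit_quiet(t[1:4, ]), "at least 5")
})

test_that("Tauc extrapolation is exact on noiseless edges for any B", {
  for (p in list(c(2.0, 1), c(2.0, 50), c(1.9, 1), c(2.1, 0.3))) {
    e <- make_tauc_edge(p[1], B = p[2], energies = seq(1.5, 3.5, by = 0.01))
    fit <- tauc_band_gap(e)
    expect_equal(fit$Eg, p[1], tolerance = 1e-6)
  }
})

test_that("Tauc recovery under 1% relative noise is accurate on average", {
  errs <- vapply(1:50, function(s) {
    e <- make_tauc_edge(2.1, B = 1, energies = seq(1.5, 3.5, by = 0.01),
                        noise = noise_model(0, 0.01, seed = s))
    tauc_band_gap(e)$Eg - 2.1
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("Tauc fails loudly when no window is linear", {
  set.seed(99)
  e <- tibble::tibble(energy_eV = seq(1.5, 3.5, 0.05),
                      alpha = runif(41, 0, 1))
  expect_error(tauc_band_gap(e, r2_min = 0.9999), "no linear region")
})

test_that("photon-energy and ionization-potential conversions match hand values", {
  expect_equal(ct_transition_energy(530), 2.339, tolerance = 1e-3)
  expect_equal(ct_transition_energy(470), 2.638, tolerance = 1e-3)
  expect_equal(ct_transition_energy(1239.84), 1)

  expect_equal(round(ionization_potential(530), 2), 8.65)
  expect_equal(round(ionization_potential(470), 2), 9.02)
  # zero-wavenumber limit
  expect_equal(ionization_potential(1e12), 5.76, tolerance = 1e-6)
  expect_error(ionization_potential(-5), "positive")

  # Ip strictly decreasing in lambda
  lam <- seq(200, 800, by = 10)
  expect_true(all(diff(ionization_potential(lam)) < 0))
})

test_that("standard free energy matches -RT ln K and flips sign at K = 1", {
  expect_equal(round(standard_free_energy(147, 298), 2), -12.36)
  expect_equal(standard_free_energy(1), 0)
  expect_equal(standard_free_energy(137, 298), -12.19, tolerance = 1e-3)
  k <- 10^seq(-2, 4, by = 0.5)
  dg <- standard_free_energy(k)
  expect_true(all(diff(dg) < 0))
  expect_true(all(dg[k > 1] < 0) && all(dg[k < 1] > 0))
  expect_error(standard_free_energy(0), "positive")
})

test_that("band-intensity descriptors require their auxiliary inputs", {
  expect_equal(oscillator_strength(1e4, 1e4), 0.432)
  expect_equal(oscillator_strength(1e4, 0), 0)
  expect_equal(transition_dipole(1e4, 0, 2e4), 0)
  expect_error(oscillator_strength(1e4), "insufficient data")
  expect_error(transition_dipole(1e4, 1e4), "insufficient data")
  expect_error(resonance_energy(8.65, 3.3), "insufficient data")
  # transition-energy balance inverts consistently
  expect_equal(resonance_energy(8.65, 3.3, 3.331, 2.339), 0.32)
})

test_that("Job's analysis finds a symmetric 1:1 maximum", {
  j <- make_job_series(2e-3, 150, 1.29e4, seq(0.1, 0.9, by = 0.1))
  fit <- jobs_ratio(j)
  expect_equal(fit$x_star, 0.5, tolerance = 1e-9)
  expect_equal(fit$ratio, 1, tolerance = 1e-8)
  expect_equal(fit$ratio_label, "1:1")
})

test_that("Job's vertex arithmetic handles a 1:2 complex shape", {
  x <- seq(0.1, 0.9, by = 0.1)
  j <- tibble::tibble(mole_fraction = x, absorbance = 1 - (x - 1 / 3)^2)
  fit <- jobs_ratio(j)
  expect_equal(fit$x_star, 1 / 3, tolerance = 1e-9)
  expect_equal(fit$ratio, 0.5, tolerance = 1e-6)
  expect_equal(fit$ratio_label, "1:2")
})

test_that("Job's estimate tolerates 0.5% noise in most seeds", {
  hits <- vapply(1:20, function(s) {
    j <- make_job_series(2e-3, 150, 1.29e4, seq(0.05, 0.95, by = 0.05),
                         noise = noise_model(0, 0.005, seed = s))
    abs(jobs_ratio(j)$x_star - 0.5) <= 0.03
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("Job's analysis is scale invariant and rejects boundary maxima", {
  j <- make_job_series(2e-3, 150, 1.29e4, seq(0.1, 0.9, by = 0.1))
  f1 <- jobs_ratio(j)
  f2 <- jobs_ratio(dplyr::mutate(j, absorbance = absorbance * 1e3))
  expect_equal(f1$x_star, f2$x_star)

  mono <- tibble::tibble(mole_fraction = seq(0.1, 0.9, by = 0.1),
                         absorbance = seq(0.1, 0.9, by = 0.1))
  expect_error(jobs_ratio(mono), "boundary")
})

test_that("donor-site ranking reproduces the charge-table scores", {
  charges <- read_charge_table(charge_table_path())
  sites <- list(
    pyrimidinyl_pyrazole_N6_N7 = c(6, 7),
    pyrrole_N12 = 12,
    none = integer(0)
  )
  ranked <- donor_site_ranking(charges, sites)
  expect_equal(ranked$site[1], "pyrimidinyl_pyrazole_N6_N7")
  expect_equal(ranked$score[ranked$site == "pyrimidinyl_pyrazole_N6_N7"], 0.735)
  expect_equal(ranked$score[ranked$site == "pyrrole_N12"], 0.7068)
  expect_equal(ranked$score[ranked$site == "none"], 0)
})

test_that("site ranking is row-order invariant and names missing atoms", {
  charges <- read_charge_table(charge_table_path())
  shuffled <- charges[sample(nrow(charges)), ]
  sites <- list(a = c(6, 7), b = c(12), c = c(2, 23))
  expect_equal(donor_site_ranking(charges, sites),
               donor_site_ranking(shuffled, sites))
  expect_error(donor_site_ranking(charges, list(x = c(6, 99))), "99")
})

test_that("mass/molar conversions reconcile the two stated concentration scales", {
  # 11.25-37.5 ug/mL at M = 306.37 g/mol spans 3.67e-5 to 1.22e-4 M
  expect_equal(ugml_to_molar(11.25), 3.67e-5, tolerance = 1e-3)
  expect_equal(ugml_to_molar(37.5), 1.22e-4, tolerance = 2e-3)
  expect_equal(molar_to_ugml(ugml_to_molar(42)), 42)
})
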
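# Independent oracles, deliberately implemented with methods different from
# the package internals.

# Bisection root of the mass-action equation K*(D0-x)*(A0-x) = x on
# [0, min(D0, A0)], iterated to machine precision.
bisect_equilibrium <- function(K, d0, a0, iters = 200) {
  if (K == 0 || d0 == 0 || a0 == 0) return(0)
  f <- function(x) K * (d0 - x) * (a0 - x) - x
  lo <- 0
  hi <- min(d0, a0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force argmax of a sum of Gaussian bands on a dense wavelength grid.
dense_gaussian_argmax <- function(bands, from, to, step = 0.01) {
  grid <- seq(from, to, by = step)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$height[i] *
      exp(-((grid - bands$center[i])^2) / (2 * bands$width[i]^2))
  }
  grid[which.max(y)]
}

charge_table_path <- function() {
  system.file("extdata", "rux_partial_charges.csv", package = "ctcassay")
}

ledger_path <- function() {
  system.file("extdata", "eco_scale_ledger.yaml", package = "ctcassay")
}
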
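# Fixtures built in code; all deterministic under explicit seeds.

# Minimal clean series with all indicator channels, given a DO vector.
make_series <- function(do, start = as.POSIXct("2021-03-01", tz = "UTC"),
                        step_minutes = 15) {
  n <- length(do)
  tibble::tibble(
    timestamp = start + step_minutes * 60 * (seq_len(n) - 1),
    do_mgl = do,
    temp_c = 12 + 0.01 * seq_len(n) %% 7,
    cond_uscm = 600,
    ph = 7.8,
    ammonium_mgl = 0.1,
    turbidity_ntu = 10,
    rainfall_mm = 0.5
  )
}

# Half-day-periodic DO with higher harmonics: exactly periodic at 48 steps
# but not a pure sinusoid, so a lag-48 copy is exact while a linear map of
# the fundamental sine/cosine phase is not.
halfday_harmonic_do <- function(n_steps) {
  phase <- 2 * pi * (seq_len(n_steps) - 1) / 48
  9 + cos(phase) + 0.5 * cos(2 * phase + 0.7) + 0.25 * cos(3 * phase + 1.1)
}

# Tidal + diel DO shape: dominated by the half-day cycle but with a daily
# asymmetry (as photosynthesis superimposes on the tide), periodic at 96
# steps, non-sinusoidal.
tidal_diel_do <- function(n_steps) {
  p48 <- 2 * pi * (seq_len(n_steps) - 1) / 48
  p96 <- 2 * pi * (seq_len(n_steps) - 1) / 96
  9 + cos(p48) + 0.6 * cos(p96 + 0.5) + 0.3 * cos(2 * p48 + 1.1)
}

# q-Gaussian CDF by numerical integration of the density (independent of
# the Student-t sampling route); linear interpolation on a fine grid.
qgauss_cdf_numeric <- function(p, lim = 2000, n_grid = 200001) {
  xs <- seq(-lim, lim, length.out = n_grid)
  d <- dqgauss(xs, p)
  cs <- cumsum((d[-1] + d[-n_grid]) / 2 * diff(xs))
  # mass beyond the grid handled by renormalising (tails are power-law)
  cdf <- c(0, cs) / max(cs)
  stats::approxfun(xs, cdf, yleft = 0, yright = 1)
}
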
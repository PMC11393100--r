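#' Configuration for the synthetic DO generator
#'
#' Describes a tidal-river dissolved-oxygen regime: a strictly positive
#' trend made of a baseline, an annual cosine (phased so summer is low) and
#' a half-day tidal cosine, multiplied by heavy-tailed fluctuations
#' `exp(sigma * z)` where `z` comes from a chi-squared superstatistical
#' mixture ([simulate_chi2_superposition()]). Companion water-quality
#' channels (temperature anticorrelated with DO, pH with a diel component,
#' conductivity, ammonium, turbidity, daily rainfall) are simple coupled
#' sinusoids plus noise — enough structure to exercise QC and feature
#' building, not a chemistry model.
#'
#' @param n_days length of the record in days.
#' @param step_minutes sampling step (15 by default, the sonde resolution).
#' @param baseline_do mean DO level, mg/L.
#' @param annual_amplitude amplitude of the annual cycle, mg/L (winter-high).
#' @param halfday_amplitude amplitude of the tidal half-day cycle, mg/L.
#' @param sigma scale of the multiplicative log-fluctuations.
#' @param fluctuation a [superstat_chi2_params()] driving the fluctuations.
#' @param additive_noise if `TRUE`, inject Gaussian fluctuations additively
#'   instead of the multiplicative-lognormal route (control experiments).
#' @param start first timestamp (UTC).
#' @param dist_to_sea_km site distance to the estuary, km.
#' @param site_id site label.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_days = 60, step_minutes = 15,
                             baseline_do = 9, annual_amplitude = 2,
                             halfday_amplitude = 1, sigma = 0.04,
                             fluctuation = superstat_chi2_params(3, 1, 50),
                             additive_noise = FALSE,
                             start = as.POSIXct("2020-01-01", tz = "UTC"),
                             dist_to_sea_km = 20, site_id = "S1", seed = 1) {
  stopifnot(inherits(fluctuation, "superstat_chi2_params"))
  if (baseline_do - annual_amplitude - halfday_amplitude <= 0) {
    stop("amplitudes leave a non-positive trend: require baseline > sum of amplitudes",
         call. = FALSE)
  }
  structure(list(n_days = n_days, step_minutes = step_minutes,
                 baseline_do = baseline_do,
                 annual_amplitude = annual_amplitude,
                 halfday_amplitude = halfday_amplitude, sigma = sigma,
                 fluctuation = fluctuation, additive_noise = additive_noise,
                 start = start, dist_to_sea_km = dist_to_sea_km,
                 site_id = site_id, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic DO monitoring site
#'
#' Emits a clean multi-indicator series with the statistical structure the
#' analysis pipeline assumes: `DO(t) = T(t) * exp(sigma * z_t)` with `T` a
#' baseline + annual (summer-low) + half-day cosine trend and `z` a
#' chi-squared superstatistical Gaussian mixture, so that multiplicative
#' detrending followed by q-Gaussian fitting is the correctly specified
#' model. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return tibble with columns `site_id`, `timestamp`, `do_mgl`, `temp_c`,
#'   `cond_uscm`, `ph`, `ammonium_mgl`, `turbidity_ntu`, `rainfall_mm`,
#'   `dist_to_sea_km`.
#' @export
#' @examples
#' s <- generate_site(synthetic_config(n_days = 3))
#' dplyr::glimpse(s)
generate_site <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  step_s <- cfg$step_minutes * 60
  n <- as.integer(round(cfg$n_days * 24 * 60 / cfg$step_minutes))
  ts <- cfg$start + step_s * (seq_len(n) - 1)

  doy <- as.numeric(difftime(ts, as.POSIXct(paste0(format(ts, "%Y"), "-01-01"),
                                            tz = "UTC"), units = "days"))
  mins <- (as.numeric(ts) / 60) %% 720       # minutes into the half-day
  trend <- cfg$baseline_do +
    cfg$annual_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    cfg$halfday_amplitude * cos(2 * pi * mins / 720)
  if (any(trend <= 0)) {
    stop("configured amplitudes produced a non-positive trend", call. = FALSE)
  }

  z <- simulate_chi2_superposition(cfg$fluctuation, n, seed = cfg$seed)
  do <- if (cfg$additive_noise) {
    pmax(trend + cfg$sigma * z, 1e-6)
  } else {
    trend * exp(cfg$sigma * z)
  }

  with_seed(cfg$seed + 1L, {
    diel <- sin(2 * pi * (as.numeric(ts) / 86400))
    temp <- 12 - 6 * cos(2 * pi * (doy - 15) / 365.25) +
      1.5 * diel + stats::rnorm(n, 0, 0.3)
    cond <- 620 + 40 * cos(2 * pi * (doy - 15) / 365.25) + stats::rnorm(n, 0, 15)
    ph <- 7.9 + 0.15 * sin(2 * pi * mins / 720) + stats::rnorm(n, 0, 0.05)
    ammonium <- exp(stats::rnorm(n, log(0.15), 0.3))
    turbidity <- exp(stats::rnorm(n, log(12), 0.4))
    days <- unique(as.Date(ts))
    rain_daily <- round(stats::rgamma(length(days), shape = 0.4, scale = 6), 1)
    rainfall <- rain_daily[match(as.Date(ts), days)]
    tibble::tibble(
      site_id = cfg$site_id, timestamp = ts, do_mgl = do, temp_c = temp,
      cond_uscm = pmax(cond, 1), ph = pmin(pmax(ph, 0.1), 14),
      ammonium_mgl = ammonium, turbidity_ntu = turbidity,
      rainfall_mm = rainfall, dist_to_sea_km = cfg$dist_to_sea_km
    )
  })
}

#' Generate a multi-site ensemble with a spatial beta gradient
#'
#' One site per distance, with the log-fluctuation scale chosen so the
#' q-Gaussian scale parameter fitted to the multiplicative-EMD
#' log-fluctuations follows `beta(d) = beta_intercept + beta_slope * d`.
#' The fitted beta of `sigma * z` scales as `beta_z / sigma^2` with
#' `beta_z = beta0_hat * (n + 1) / (2 n)` the scale of the mixture's
#' q-Gaussian marginal, so `sigma(d) = sqrt(beta_z / beta(d))`. Per-site
#' seeds derive from `base$seed`.
#'
#' @param base a [synthetic_config()] used as the template.
#' @param distances numeric vector of site distances to the sea, km.
#' @param beta_slope change of the target scale parameter per km.
#' @param beta_intercept target scale parameter at the estuary (d = 0).
#' @return tibble of all sites row-bound together (see [generate_site()]).
#' @export
generate_multisite <- function(base, distances, beta_slope, beta_intercept) {
  stopifnot(inherits(base, "synthetic_config"), length(distances) >= 1)
  beta_target <- beta_intercept + beta_slope * distances
  if (any(beta_target <= 0)) {
    stop("implied beta is non-positive at some distance", call. = FALSE)
  }
  nd <- base$fluctuation$n_dof
  beta_z <- base$fluctuation$beta0_hat * (nd + 1) / (2 * nd)
  purrr::map2_dfr(seq_along(distances), distances, function(i, d) {
    cfg <- base
    cfg$site_id <- sprintf("S%02d", i)
    cfg$dist_to_sea_km <- d
    cfg$sigma <- sqrt(beta_z / beta_target[i])
    cfg$seed <- base$seed + 1000L * i
    generate_site(cfg)
  })
}
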
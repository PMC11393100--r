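#' Linear trend of a fitted parameter against distance to sea
#'
#' Ordinary least squares of a fitted q-Gaussian parameter (`beta` or `q`)
#' on site distance-to-sea, with Pearson correlation and a seeded
#' permutation p-value for the correlation (the estimator the trend plots
#' imply, plus a distribution-free significance check).
#'
#' @param records data frame with one row per (site, variant): columns
#'   `dist_to_sea_km` and the parameter column named by `param`. Filter to
#'   a single detrending variant before calling; trends are per variant.
#' @param param which parameter to regress: `"beta"` or `"q"`.
#' @param n_perm number of permutations for the p-value.
#' @param seed seed for the permutation draw.
#' @return list of class `distance_trend`: `slope`, `intercept`,
#'   `correlation`, `slope_se`, `p_perm`, `n`, `param`, and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' rec <- tibble::tibble(dist_to_sea_km = c(5, 15, 30, 45),
#'                       beta = c(40, 35, 28, 20))
#' fit_distance_trend(rec, "beta")$slope
fit_distance_trend <- function(records, param = c("beta", "q"),
                               n_perm = 10000, seed = 1) {
  param <- match.arg(param)
  stopifnot(is.data.frame(records), param %in% names(records),
            "dist_to_sea_km" %in% names(records))
  d <- records$dist_to_sea_km
  v <- records[[param]]
  ok <- is.finite(d) & is.finite(v)
  d <- d[ok]; v <- v[ok]
  if (length(d) < 3) stop("need at least 3 sites", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("all distances are equal: the design is degenerate", call. = FALSE)
  }
  fit <- stats::lm(v ~ d)
  n <- length(d)
  slope_se <- sqrt(sum(stats::resid(fit)^2) / (n - 2) /
                     sum((d - mean(d))^2))
  r <- stats::cor(d, v)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(d, sample(v))
  }, numeric(1)))
  p_perm <- (1 + sum(abs(r_perm) >= abs(r))) / (n_perm + 1)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    correlation = r,
    slope_se = slope_se,
    p_perm = p_perm, n = n, param = param, lm_fit = fit
  ), class = "distance_trend")
}

#' @export
print.distance_trend <- function(x, ...) {
  cat(sprintf("Distance trend of %s: slope = %.4g (SE %.3g) per km, r = %.3f, permutation p = %.4g (n = %d)\n",
              x$param, x$slope, x$slope_se, x$correlation, x$p_perm, x$n))
  invisible(x)
}

#' Fit q-Gaussians per site and collect parameter records
#'
#' Convenience wrapper for the spatial analysis: detrends the DO column of
#' each site with one variant, fits the q-Gaussian, and emits one record
#' per site suitable for [fit_distance_trend()].
#'
#' @param sites tibble of stacked site series (as from
#'   [generate_multisite()]): needs `site_id`, `do_mgl`, `dist_to_sea_km`.
#' @param method,mode detrending variant applied to every site.
#' @param ... passed to [detrend()].
#' @return tibble with `site_id`, `dist_to_sea_km`, `variant`, `q`, `beta`,
#'   `mean_loglik`, `converged`.
#' @export
fit_sites_qgauss <- function(sites, method = "emd", mode = "multiplicative",
                             ...) {
  stopifnot(all(c("site_id", "do_mgl", "dist_to_sea_km") %in% names(sites)))
  sites |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(df, key) {
      d <- detrend(df$do_mgl, method = method, mode = mode, ...)
      fit <- fit_qgauss_mle(centered_fluctuations(d))
      tibble::tibble(
        dist_to_sea_km = df$dist_to_sea_km[1],
        variant = paste(mode, method, sep = "-"),
        q = fit$params$q, beta = fit$params$beta,
        mean_loglik = fit$mean_log_likelihood, converged = fit$converged
      )
    }) |>
    dplyr::ungroup()
}
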
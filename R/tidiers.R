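#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a q-Gaussian fit
#'
#' @param x a `qgauss_fit` from [fit_qgauss_mle()].
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy qgauss_fit
#' @export
tidy.qgauss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("q", "beta", "mu"),
    estimate = c(x$params$q, x$params$beta, x$params$mu),
    std.error = unname(x$stderr)
  )
}

#' One-row summary of a q-Gaussian fit
#'
#' @param x a `qgauss_fit`.
#' @param ... unused.
#' @return tibble with `q`, `beta`, `mu`, `logLik`, `mean_logLik`,
#'   `variance` (Inf when q >= 5/3), `nobs`, `converged`.
#' @method glance qgauss_fit
#' @export
glance.qgauss_fit <- function(x, ...) {
  tibble::tibble(
    q = x$params$q, beta = x$params$beta, mu = x$params$mu,
    logLik = x$log_likelihood, mean_logLik = x$mean_log_likelihood,
    variance = qgauss_variance(x$params),
    nobs = x$n_obs, converged = x$converged
  )
}

#' Tidy a distance trend
#'
#' @param x a `distance_trend` from [fit_distance_trend()].
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error` rows for intercept
#'   and slope.
#' @method tidy distance_trend
#' @export
tidy.distance_trend <- function(x, ...) {
  d <- stats::model.frame(x$lm_fit)$d
  sigma2 <- sum(stats::resid(x$lm_fit)^2) / (x$n - 2)
  se_int <- sqrt(sigma2 * (1 / x$n + mean(d)^2 / sum((d - mean(d))^2)))
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(se_int, x$slope_se)
  )
}

#' One-row summary of a distance trend
#'
#' @param x a `distance_trend`.
#' @param ... unused.
#' @return tibble with `param`, `slope`, `slope_se`, `intercept`,
#'   `correlation`, `p_perm`, `nobs`.
#' @method glance distance_trend
#' @export
glance.distance_trend <- function(x, ...) {
  tibble::tibble(
    param = x$param, slope = x$slope, slope_se = x$slope_se,
    intercept = x$intercept, correlation = x$correlation,
    p_perm = x$p_perm, nobs = x$n
  )
}
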
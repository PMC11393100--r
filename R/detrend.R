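#' Centered moving-average trend
#'
#' Extracts a slow trend with a centered moving average whose window spans
#' the filtering frequency `f_hours`. An even sample count `w` uses the
#' classic symmetric 2-by-w weights (half weight on the two outermost
#' points, as in classical seasonal decomposition), so linear signals are
#' preserved and a sinusoid of period exactly `f_hours` averages to zero.
#' At the boundaries the centered window shrinks to the valid range with
#' renormalised weights; no padding is fabricated.
#'
#' @param y numeric series.
#' @param f_hours filtering frequency in hours (window duration).
#' @param step_minutes sampling step in minutes (default 15).
#' @return numeric trend, same length as `y`.
#' @export
#' @examples
#' moving_average_trend(rep(3, 100), f_hours = 6)[1:5]
moving_average_trend <- function(y, f_hours, step_minutes = 15) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  w <- round(60 * f_hours / step_minutes)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  n <- length(y)
  if (w >= n) stop("moving-average window longer than the series", call. = FALSE)
  if (w %% 2 == 1) {
    wts <- rep(1, w)
  } else {
    wts <- c(0.5, rep(1, w - 1), 0.5)   # symmetric 2 x w average
  }
  h <- (length(wts) - 1L) %/% 2L
  wsum <- cumsum(wts)
  out <- numeric(n)
  # interior via filter (fast), boundaries by shrunk renormalised windows
  filt <- stats::filter(y, wts / sum(wts), sides = 2)
  out[] <- as.numeric(filt)
  for (i in which(is.na(out))) {
    j <- max(1L, i - h):min(n, i + h)
    ww <- wts[j - i + h + 1L]
    out[i] <- sum(y[j] * ww) / sum(ww)
  }
  out
}

#' Seasonal (moving-average) detrending
#'
#' Splits a series into a slow trend and fast fluctuations around it. In
#' additive mode the fluctuation is `y - trend`; in multiplicative mode the
#' whole procedure runs on `log(y)` and is exponentiated back, so the
#' fluctuation is the ratio `y / trend` and `trend * fluctuation`
#' reconstructs `y` exactly. Any remainder is folded into the fluctuation.
#'
#' @param y numeric series (strictly positive for multiplicative mode).
#' @param f_hours filtering frequency in hours.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param step_minutes sampling step in minutes.
#' @return A `decomposition` object: list with `mode`, `method`
#'   (`"seasonal"`), `trend`, `fluctuation`, and `params`.
#' @export
#' @examples
#' y <- 9 + sin(seq(0, 20, length.out = 500))
#' d <- seasonal_detrend(y, f_hours = 6, mode = "additive")
#' max(abs(d$trend + d$fluctuation - y))
seasonal_detrend <- function(y, f_hours = 6, mode = c("additive", "multiplicative"),
                             step_minutes = 15) {
  mode <- match.arg(mode)
  if (mode == "multiplicative") {
    check_positive(y, "multiplicative seasonal detrending")
    trend <- exp(moving_average_trend(log(y), f_hours, step_minutes))
    fluct <- y / trend
  } else {
    trend <- moving_average_trend(y, f_hours, step_minutes)
    fluct <- y - trend
  }
  new_decomposition(mode, "seasonal", trend, fluct,
                    params = list(f_hours = f_hours))
}

#' EMD detrending
#'
#' Runs [emd()] and splits the modes: the `m_dropped` fastest IMFs form the
#' fluctuation; the remaining (slow) IMFs form the trend. The residue — the
#' slowest component of all — goes to the trend by default so fluctuations
#' are centered (near 0 additive, near 1 multiplicative); `residue_to =
#' "fluctuation"` keeps it with the fluctuation instead. Multiplicative
#' mode runs the whole procedure on `log(y)` and exponentiates back, so
#' `trend * fluctuation` reconstructs `y` exactly.
#'
#' The number of dropped modes is a per-site analysis choice. `m_dropped =
#' "auto"` selects it by aligning the EMD cut with a filtering frequency:
#' every IMF whose dominant period is shorter than `cutoff_hours` goes to
#' the fluctuation, which makes the EMD variants directly comparable with
#' seasonal detrending at filter frequency `f = cutoff_hours`.
#'
#' @param y numeric series (strictly positive for multiplicative mode).
#' @param m_dropped number of fastest modes assigned to the fluctuation,
#'   between 1 and the number of extracted IMFs, or `"auto"`.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param residue_to `"trend"` (default) or `"fluctuation"`.
#' @param cutoff_hours period cutoff used when `m_dropped = "auto"`.
#' @param step_minutes sampling step, used only by `m_dropped = "auto"`.
#' @param ... passed to [emd()].
#' @return A `decomposition` object (see [seasonal_detrend()]) with
#'   `method = "emd"` and the [emd()] result attached as `$imf_set`.
#' @export
emd_detrend <- function(y, m_dropped = 3, mode = c("additive", "multiplicative"),
                        residue_to = c("trend", "fluctuation"),
                        cutoff_hours = 6, step_minutes = 15, ...) {
  mode <- match.arg(mode)
  residue_to <- match.arg(residue_to)
  if (mode == "multiplicative") {
    check_positive(y, "multiplicative EMD detrending")
    work <- log(y)
  } else {
    work <- y
  }
  dec <- emd(work, ...)
  N <- dec$n_imfs
  if (N == 0) stop("no intrinsic mode functions extracted (monotone signal?)",
                   call. = FALSE)
  if (identical(m_dropped, "auto")) {
    m_dropped <- choose_m_dropped(dec, cutoff_hours, step_minutes)
  }
  if (m_dropped < 1 || m_dropped > N) {
    stop(sprintf("`m_dropped` must be in 1..%d (number of IMFs), got %s",
                 N, m_dropped), call. = FALSE)
  }
  zero <- rep(0, length(y))
  slow <- if (m_dropped < N) Reduce(`+`, dec$imfs[seq_len(N - m_dropped)], zero) else zero
  fast <- Reduce(`+`, dec$imfs[seq.int(N - m_dropped + 1L, N)], zero)
  if (residue_to == "trend") {
    trend <- slow + dec$residue
    fluct <- fast
  } else {
    trend <- slow
    fluct <- fast + dec$residue
  }
  if (mode == "multiplicative") {
    trend <- exp(trend)
    fluct <- exp(fluct)
  }
  out <- new_decomposition(mode, "emd", trend, fluct,
                           params = list(m_dropped = m_dropped,
                                         residue_to = residue_to,
                                         n_imfs = N))
  out$imf_set <- dec
  out
}

#' Detrend a series by any of the four variants
#'
#' Thin dispatcher over [seasonal_detrend()] and [emd_detrend()], handy for
#' mapping over variant tables.
#'
#' @param y numeric series.
#' @param method `"seasonal"` or `"emd"`.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param f_hours filtering frequency (seasonal method).
#' @param m_dropped dropped fast-mode count (EMD method).
#' @param ... passed on to the method.
#' @return A `decomposition` object.
#' @export
detrend <- function(y, method = c("seasonal", "emd"),
                    mode = c("additive", "multiplicative"),
                    f_hours = 6, m_dropped = 3, ...) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  switch(method,
         seasonal = seasonal_detrend(y, f_hours = f_hours, mode = mode, ...),
         emd = emd_detrend(y, m_dropped = m_dropped, mode = mode, ...))
}

#' Reconstruct the input from a decomposition
#'
#' @param d a `decomposition` object.
#' @return `trend + fluctuation` (additive) or `trend * fluctuation`
#'   (multiplicative).
#' @export
reconstruct <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  if (d$mode == "additive") d$trend + d$fluctuation else d$trend * d$fluctuation
}

#' Centered fluctuation sample of a decomposition
#'
#' Prepares the fluctuation series for distribution fitting: additive
#' fluctuations have their sample mean subtracted; multiplicative
#' fluctuations are divided by their sample mean and shifted by -1, so both
#' modes yield zero-centered samples.
#'
#' @param d a `decomposition` object.
#' @return numeric vector of centered fluctuations.
#' @export
centered_fluctuations <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  f <- d$fluctuation
  if (d$mode == "additive") f - mean(f) else f / mean(f) - 1
}

new_decomposition <- function(mode, method, trend, fluctuation, params) {
  structure(list(mode = mode, method = method, trend = trend,
                 fluctuation = fluctuation, params = params),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("%s %s decomposition, n = %d\n", x$mode, x$method,
              length(x$trend)))
  invisible(x)
}

#' Choose the number of dropped EMD modes by a period cutoff
#'
#' Counts, from the fast end, the IMFs whose dominant periodogram period
#' is shorter than `cutoff_hours`; stops at the first slower mode so the
#' selection is contiguous in the mode ordering. At least one mode is
#' always dropped.
#'
#' @param imf_set an [emd()] result.
#' @param cutoff_hours period cutoff in hours.
#' @param step_minutes sampling step in minutes.
#' @return integer count of fast modes to assign to the fluctuation.
#' @export
choose_m_dropped <- function(imf_set, cutoff_hours = 6, step_minutes = 15) {
  stopifnot(inherits(imf_set, "imf_set"), imf_set$n_imfs >= 1)
  n <- length(imf_set$residue)
  m <- 0L
  for (i in seq.int(imf_set$n_imfs, 1L)) {     # fast -> slow
    imf <- imf_set$imfs[[i]]
    pw <- Mod(stats::fft(imf))^2
    half <- 2:(floor(n / 2) + 1)
    j <- which.max(pw[half])                   # dominant nonzero frequency
    period_h <- (n / j) * step_minutes / 60
    if (period_h < cutoff_hours) m <- m + 1L else break
  }
  max(m, 1L)
}

check_positive <- function(y, what) {
  bad <- which(y <= 0)
  if (length(bad)) {
    stop(sprintf("%s requires strictly positive values; first offending index: %d",
                 what, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}
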
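#' Build the fourteen-covariate feature matrix
#'
#' Augments a clean series with calendar and periodic encodings: the seven
#' measured channels (DO, temperature, conductivity, pH, ammonium,
#' turbidity, rainfall), hour-of-day, day-of-week and month-of-year each
#' affinely mapped into \[-0.5, 0.5\] (`hour/23 - 0.5`, `weekday/6 - 0.5`,
#' `(month-1)/11 - 0.5`), and sine/cosine of the half-day phase
#' (`2 * pi * minutes-since-00:00-or-12:00 / 720`) and of the year phase.
#' Fourteen covariates in total; DO is both a covariate and the target.
#'
#' @param s tibble with `timestamp` and the seven measured channels.
#' @return tibble with `timestamp`, the 14 covariate columns (see
#'   [feature_columns()]) and `do_mgl` as the target.
#' @export
#' @examples
#' s <- generate_site(synthetic_config(n_days = 2))
#' ncol(build_features(s)[, feature_columns()])
build_features <- function(s) {
  need <- c("timestamp", "do_mgl", "temp_c", "cond_uscm", "ph",
            "ammonium_mgl", "turbidity_ntu", "rainfall_mm")
  missing <- setdiff(need, names(s))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ts <- s$timestamp
  secs <- as.numeric(ts)
  half_phase <- 2 * pi * ((secs / 60) %% 720) / 720
  year_start <- as.POSIXct(paste0(format(ts, "%Y"), "-01-01"), tz = "UTC")
  year_len <- ifelse(lubridate::leap_year(ts), 366, 365) * 86400
  year_phase <- 2 * pi * (secs - as.numeric(year_start)) / year_len
  tibble::tibble(
    timestamp = ts,
    do_mgl = s$do_mgl, temp_c = s$temp_c, cond_uscm = s$cond_uscm,
    ph = s$ph, ammonium_mgl = s$ammonium_mgl,
    turbidity_ntu = s$turbidity_ntu, rainfall_mm = s$rainfall_mm,
    hour_enc = lubridate::hour(ts) / 23 - 0.5,
    dow_enc = (lubridate::wday(ts, week_start = 1) - 1) / 6 - 0.5,
    month_enc = (lubridate::month(ts) - 1) / 11 - 0.5,
    sin_halfday = sin(half_phase), cos_halfday = cos(half_phase),
    sin_year = sin(year_phase), cos_year = cos(year_phase)
  )
}

#' Names of the fourteen forecasting covariates
#' @return character vector of length 14.
#' @export
feature_columns <- function() {
  c("do_mgl", "temp_c", "cond_uscm", "ph", "ammonium_mgl", "turbidity_ntu",
    "rainfall_mm", "hour_enc", "dow_enc", "month_enc",
    "sin_halfday", "cos_halfday", "sin_year", "cos_year")
}

#' Dominant periodogram frequencies
#'
#' Top-k local maxima of the FFT periodogram, zero frequency excluded.
#' Used to confirm which periodicities matter in a DO record (for tidal
#' rivers: near one cycle per year and one per half-day).
#'
#' @param y regularly sampled numeric series, length >= 2k.
#' @param k number of peaks to return.
#' @param step_minutes sampling step.
#' @param timestamps optional POSIXct vector; if supplied, sampling
#'   regularity is checked and irregular spacing is an error.
#' @return tibble with `frequency_per_day`, `period_days`, `power`,
#'   ordered by descending power.
#' @export
fft_dominant_frequencies <- function(y, k = 5, step_minutes = 15,
                                     timestamps = NULL) {
  stopifnot(is.numeric(y), length(y) >= 2 * k)
  if (!is.null(timestamps)) {
    dt <- diff(as.numeric(timestamps))
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
      stop("irregular sampling: resample before the FFT", call. = FALSE)
    }
    step_minutes <- dt[1] / 60
  }
  n <- length(y)
  pw <- Mod(stats::fft(y - mean(y)))^2 / n
  m <- floor(n / 2)
  pw <- pw[2:(m + 1)]                      # drop zero frequency
  freq <- (1:m) / (n * step_minutes / (60 * 24))   # cycles per day
  is_peak <- pw >= c(0, pw[-m]) & pw >= c(pw[-1], 0)
  idx <- which(is_peak)
  idx <- idx[order(pw[idx], decreasing = TRUE)]
  idx <- utils::head(idx, k)
  tibble::tibble(frequency_per_day = freq[idx],
                 period_days = 1 / freq[idx],
                 power = pw[idx])
}

#' Chronological train/validation/test windows
#'
#' Splits the rows chronologically by `fractions` (no shuffling across the
#' split boundary), computes per-column normalisation statistics from the
#' training rows only, and enumerates forecast windows of `input_len`
#' covariate steps followed by `horizon` DO targets. A window never
#' crosses a split boundary or a sampling gap (consecutive timestamps more
#' than one nominal step apart). Training window order is shuffled under
#' the seed; validation and test stay chronological.
#'
#' @param f feature tibble from [build_features()].
#' @param input_len input window length in steps (e.g. 48, 96, 192).
#' @param horizon forecast horizon in steps (e.g. 1, 12, 24, 48).
#' @param fractions train/validation/test fractions, summing to 1.
#' @param seed seed for the training-window shuffle.
#' @param step_minutes nominal sampling step.
#' @return A `forecast_dataset`: list with the raw `features` matrix,
#'   `do` target vector, `timestamps`, normalisation `center`/`scale`,
#'   per-split window origin indices (`origins$train` etc., an origin
#'   being the index of the last input step), and the geometry fields.
#' @export
make_windows <- function(f, input_len, horizon,
                         fractions = c(0.7, 0.2, 0.1), seed = 1,
                         step_minutes = 15) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3,
            input_len >= 1, horizon >= 1)
  n <- nrow(f)
  cols <- feature_columns()
  stopifnot(all(cols %in% names(f)))
  X <- as.matrix(f[, cols])
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  bounds <- list(train = c(1L, n_train),
                 val = c(n_train + 1L, n_train + n_val),
                 test = c(n_train + n_val + 1L, n))

  center <- colMeans(X[seq_len(n_train), , drop = FALSE])
  scale <- apply(X[seq_len(n_train), , drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1

  # segment id increments at every sampling gap
  gap <- c(FALSE, diff(as.numeric(f$timestamp)) > step_minutes * 60 * 1.5)
  seg <- cumsum(gap)

  origins <- lapply(bounds, function(b) {
    lo <- b[1] + input_len - 1L
    hi <- b[2] - horizon
    if (hi < lo) return(integer())
    cand <- lo:hi
    ok <- seg[cand - input_len + 1L] == seg[cand + horizon]
    cand[ok]
  })
  if (length(origins$train) == 0) {
    stop("training split too short for a single window", call. = FALSE)
  }
  origins$train <- with_seed(seed, sample(origins$train))

  structure(list(features = X, do = f$do_mgl, timestamps = f$timestamp,
                 center = center, scale = scale, origins = origins,
                 input_len = input_len, horizon = horizon,
                 fractions = fractions, bounds = bounds),
            class = "forecast_dataset")
}

#' @export
print.forecast_dataset <- function(x, ...) {
  cat(sprintf("forecast dataset: input %d steps -> horizon %d steps\n",
              x$input_len, x$horizon))
  cat(sprintf("  windows: %d train / %d val / %d test\n",
              length(x$origins$train), length(x$origins$val),
              length(x$origins$test)))
  invisible(x)
}

#' Normalised feature matrix of a forecast dataset
#' @param ds a `forecast_dataset`.
#' @return matrix of z-scored covariates (training statistics).
#' @export
normalized_features <- function(ds) {
  stopifnot(inherits(ds, "forecast_dataset"))
  sweep(sweep(ds$features, 2, ds$center), 2, ds$scale, "/")
}

#' True DO targets for each window of a split
#' @param ds a `forecast_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return matrix (windows x horizon) of raw DO values.
#' @export
window_targets <- function(ds, split = "test") {
  o <- split_origins(ds, split)
  outer(o, seq_len(ds$horizon), function(i, j) ds$do[i + j])
}

split_origins <- function(ds, split) {
  stopifnot(inherits(ds, "forecast_dataset"),
            split %in% c("train", "val", "test"))
  o <- ds$origins[[split]]
  if (length(o) == 0) stop("no windows in split `", split, "`", call. = FALSE)
  o
}

#' "Last" forecasting baseline (persistence)
#'
#' Repeats the last observed DO value of each input window across the
#' whole horizon.
#'
#' @param ds a `forecast_dataset`.
#' @param split evaluation split.
#' @return matrix (windows x horizon) of forecasts, raw DO scale.
#' @export
baseline_last <- function(ds, split = "test") {
  o <- split_origins(ds, split)
  matrix(ds$do[o], nrow = length(o), ncol = ds$horizon)
}

#' "Repeat" forecasting baseline (seasonal naive, half-day period)
#'
#' Repeats the initial steps of the previous half-day: the forecast window
#' is preceded by the most recent half-day block, and the block before
#' that one — the 48-step block ending `offset` steps before the origin —
#' supplies the forecast, `yhat[j] = do[origin - offset - period + j]`.
#' With the defaults (`period = offset = 48`) this copies DO from exactly
#' one day earlier, so any series that is half-day periodic (and hence
#' day-periodic) is forecast exactly, and the error distribution is the
#' same at every horizon step. `offset = 0` gives the alternative
#' alignment that copies from the block ending at the origin itself.
#'
#' @param ds a `forecast_dataset` with `input_len >= period + offset`.
#' @param split evaluation split.
#' @param period the repeat period in steps (48 = half a day at 15 min).
#' @param offset how many steps before the origin the source block ends.
#' @return matrix (windows x horizon) of forecasts.
#' @export
baseline_repeat <- function(ds, split = "test", period = 48L, offset = 48L) {
  need <- period + offset
  if (ds$input_len < need) {
    stop(sprintf("`Repeat` needs at least %d steps of history (input_len = %d)",
                 need, ds$input_len), call. = FALSE)
  }
  if (ds$horizon > period) {
    stop("horizon longer than the repeat period", call. = FALSE)
  }
  o <- split_origins(ds, split)
  outer(o, seq_len(ds$horizon),
        function(i, j) ds$do[i - offset - period + j])
}

#' Linear forecasting baseline
#'
#' Least-squares affine map from the final input step's fourteen
#' normalised covariates to the horizon-vector of DO targets, fitted on
#' the training windows. A rank-deficient design falls back to a tiny
#' ridge (`1e-8 * mean diagonal`), flagged in the result.
#'
#' @param ds a `forecast_dataset`.
#' @return object of class `linear_baseline` with the coefficient matrix.
#' @export
baseline_linear_fit <- function(ds) {
  o <- split_origins(ds, "train")
  Z <- cbind(1, normalized_features(ds)[o, , drop = FALSE])
  Y <- outer(o, seq_len(ds$horizon), function(i, j) ds$do[i + j])
  G <- crossprod(Z)
  ridge_used <- FALSE
  sol <- tryCatch(solve(G, crossprod(Z, Y)), error = function(e) NULL)
  if (is.null(sol)) {
    ridge_used <- TRUE
    lambda <- 1e-8 * mean(diag(G))
    sol <- solve(G + diag(lambda, ncol(G)), crossprod(Z, Y))
  }
  structure(list(coef = sol, ridge_used = ridge_used,
                 horizon = ds$horizon), class = "linear_baseline")
}

#' @rdname baseline_linear_fit
#' @param fit a fitted `linear_baseline`.
#' @param split evaluation split.
#' @return matrix (windows x horizon) of forecasts.
#' @export
baseline_linear_predict <- function(fit, ds, split = "test") {
  stopifnot(inherits(fit, "linear_baseline"))
  o <- split_origins(ds, split)
  Z <- cbind(1, normalized_features(ds)[o, , drop = FALSE])
  Z %*% fit$coef
}

#' Forecast error metrics per horizon
#'
#' Mean absolute error and symmetric mean absolute percentage error at
#' each requested horizon step, over all evaluated windows:
#' \deqn{MAE_t = \frac{1}{n}\sum_i |y_{i,t} - \hat y_{i,t}|, \qquad
#'   SMAPE_t = \frac{100}{n}\sum_i
#'   \frac{|y_{i,t} - \hat y_{i,t}|}{|y_{i,t}| + |\hat y_{i,t}|}.}
#' The SMAPE denominator is `|y| + |yhat|` with no factor 2, reported in
#' percent, so it is bounded by 100 for positive series; a 0/0 term is
#' defined as 0 (exact agreement).
#'
#' @param forecasts matrix (windows x horizon).
#' @param truths matrix of identical shape.
#' @param horizons horizon steps to report (must be <= ncol).
#' @param model label recorded in the output.
#' @return tibble with `model`, `horizon`, `mae`, `smape`, `n`.
#' @export
#' @examples
#' evaluate_forecast(matrix(1), matrix(3))
evaluate_forecast <- function(forecasts, truths,
                              horizons = NULL, model = "model") {
  forecasts <- as.matrix(forecasts); truths <- as.matrix(truths)
  if (!all(dim(forecasts) == dim(truths))) {
    stop("forecast and truth matrices must be the same shape", call. = FALSE)
  }
  horizons <- horizons %||% seq_len(ncol(truths))
  stopifnot(all(horizons >= 1), all(horizons <= ncol(truths)))
  purrr::map_dfr(horizons, function(t) {
    y <- truths[, t]; yh <- forecasts[, t]
    ae <- abs(y - yh)
    den <- abs(y) + abs(yh)
    sm <- ifelse(den == 0, 0, ae / den)
    tibble::tibble(model = model, horizon = as.integer(t),
                   mae = mean(ae), smape = 100 * mean(sm),
                   n = length(y))
  })
}

#' Run and score the three baselines on one dataset
#'
#' @param ds a `forecast_dataset`.
#' @param horizons horizon steps to report.
#' @param split evaluation split.
#' @return tibble of [evaluate_forecast()] rows for `last`, `repeat`,
#'   `linear`.
#' @export
evaluate_baselines <- function(ds, horizons = NULL, split = "test") {
  truths <- window_targets(ds, split)
  lin <- baseline_linear_fit(ds)
  dplyr::bind_rows(
    evaluate_forecast(baseline_last(ds, split), truths, horizons, "last"),
    evaluate_forecast(baseline_repeat(ds, split), truths, horizons, "repeat"),
    evaluate_forecast(baseline_linear_predict(lin, ds, split), truths,
                      horizons, "linear")
  )
}
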
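test_that("windows respect chronology and training-only normalisation", {
  s <- make_series(halfday_harmonic_do(1000))
  f <- build_features(s)
  ds <- make_windows(f, input_len = 48, horizon = 12, seed = 1)
  n_train <- floor(0.7 * 1000)
  # every train window's last target precedes the first validation row
  expect_true(all(ds$origins$train + ds$horizon <= n_train))
  expect_true(all(ds$origins$val - ds$input_len + 1 > n_train))
  # normalisation statistics come from training rows only
  Xtr <- ds$features[seq_len(n_train), ]
  expect_equal(unname(ds$center), unname(colMeans(Xtr)))
  # normalise-then-denormalise round trip
  Z <- normalized_features(ds)
  back <- sweep(sweep(Z, 2, ds$scale, "*"), 2, ds$center, "+")
  expect_lt(max(abs(back - ds$features)), 1e-10)
})

test_that("windows never span a sampling gap and counts reconcile", {
  s <- make_series(halfday_harmonic_do(500))
  s_gap <- s[-(201:230), ]          # half-day outage
  f <- build_features(s_gap)
  ds <- make_windows(f, input_len = 48, horizon = 12,
                     fractions = c(0.8, 0.1, 0.1), seed = 1)
  # no valid window straddles the gap row (row 200/201 boundary)
  for (o in unlist(ds$origins)) {
    rng <- (o - ds$input_len + 1):(o + ds$horizon)
    dt <- diff(as.numeric(f$timestamp[rng]))
    expect_true(all(dt == 900))
  }
  # every in-split origin is either usable or excluded by the gap/edges
  n <- nrow(f); n_train <- floor(0.8 * n)
  cand <- 48:(n_train - 12)
  gap_hit <- vapply(cand, function(o) {
    any(diff(as.numeric(f$timestamp[(o - 47):(o + 12)])) != 900)
  }, logical(1))
  expect_setequal(ds$origins$train, cand[!gap_hit])
  expect_error(make_windows(f[1:40, ], 48, 12), "too short")
})

test_that("the Last baseline repeats the final observed DO", {
  s <- make_series(halfday_harmonic_do(600))
  f <- build_features(s)
  ds <- make_windows(f, input_len = 48, horizon = 1, seed = 1)
  fc <- baseline_last(ds, "test")
  expect_equal(fc[, 1], ds$do[ds$origins$test])
  # constant input: zero error at every horizon
  sc <- make_series(rep(7, 600))
  dsc <- make_windows(build_features(sc), 48, 12, seed = 1)
  rep_c <- evaluate_forecast(baseline_last(dsc), window_targets(dsc),
                             model = "last")
  expect_true(all(rep_c$mae == 0))
})

test_that("the Repeat baseline is exact on half-day-periodic data and lagged otherwise", {
  s <- make_series(halfday_harmonic_do(2000))
  f <- build_features(s)
  ds <- make_windows(f, input_len = 144, horizon = 48, seed = 1)
  fc <- baseline_repeat(ds)
  truth <- window_targets(ds)
  expect_lt(max(abs(fc - truth)), 1e-10)
  # horizon 48 copies the whole source half-day block
  o <- ds$origins$test[1]
  expect_equal(fc[1, ], ds$do[(o - 95):(o - 48)])
  # a period that does not divide the repeat lag leaves a phase error
  s11 <- make_series(9 + sin(2 * pi * seq_len(2000) / 44))   # 11-h period
  ds11 <- make_windows(build_features(s11), 144, 48, seed = 1)
  r11 <- evaluate_forecast(baseline_repeat(ds11), window_targets(ds11),
                           horizons = c(1, 24))
  expect_true(all(r11$mae > 0.1))
  # insufficient history is a hard error
  ds_short <- make_windows(f, 48, 12, seed = 1)
  expect_error(baseline_repeat(ds_short), "history")
  # the alternative alignment sources the block ending at the origin
  fc0 <- baseline_repeat(ds, offset = 0)
  expect_equal(fc0[1, ], ds$do[(o - 47):o])
})

test_that("the Linear baseline interpolates a linear truth and tracks noise MAE", {
  n <- 3000
  phase <- 2 * pi * (seq_len(n) - 1) / 48
  s <- make_series(8 + 1.5 * sin(phase) + 0.8 * cos(phase))
  f <- build_features(s)
  ds <- make_windows(f, input_len = 48, horizon = 12, seed = 1)
  fit <- baseline_linear_fit(ds)
  tr_rep <- evaluate_forecast(baseline_linear_predict(fit, ds, "train"),
                              window_targets(ds, "train"))
  expect_lt(max(tr_rep$mae), 1e-6)
  # additive Gaussian noise: test MAE approaches sigma * sqrt(2/pi)
  sigma <- 0.3
  s2 <- s
  s2$do_mgl <- s$do_mgl + withr::with_seed(10, rnorm(n, 0, sigma))
  ds2 <- make_windows(build_features(s2), 48, 12, seed = 1)
  fit2 <- baseline_linear_fit(ds2)
  te_rep <- evaluate_forecast(baseline_linear_predict(fit2, ds2, "test"),
                              window_targets(ds2, "test"))
  expect_equal(mean(te_rep$mae), sigma * sqrt(2 / pi), tolerance = 0.1)
})

test_that("error metrics follow their printed definitions and symmetries", {
  # single pair y = 3, yhat = 1: MAE 2, SMAPE (2/4)*100 = 50%
  r <- evaluate_forecast(matrix(1), matrix(3))
  expect_equal(r$mae, 2)
  expect_equal(r$smape, 50)
  # perfect forecast
  r0 <- evaluate_forecast(matrix(1:4, 2), matrix(1:4, 2))
  expect_true(all(r0$mae == 0) && all(r0$smape == 0))
  # symmetry in y and yhat
  a <- matrix(runif(20, 1, 10), 5); b <- matrix(runif(20, 1, 10), 5)
  expect_equal(evaluate_forecast(a, b)$smape, evaluate_forecast(b, a)$smape)
  # MAE scale-equivariant, SMAPE scale-invariant, bounded
  r1 <- evaluate_forecast(a, b); r2 <- evaluate_forecast(3 * a, 3 * b)
  expect_equal(r2$mae, 3 * r1$mae)
  expect_equal(r2$smape, r1$smape)
  expect_true(all(r1$smape >= 0 & r1$smape <= 100))
  # 0/0 terms count as exact agreement
  expect_equal(evaluate_forecast(matrix(0), matrix(0))$smape, 0)
  expect_error(evaluate_forecast(matrix(1), matrix(1:2)), "shape")
})
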